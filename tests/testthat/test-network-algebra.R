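test_that("union deduplicates pairs and applies the weight rule", {
  a <- edge_tbl("a", "x", 0.2, "mm", "mean")
  b <- edge_tbl("b", "y", 0.4, "TT", "mean")
  u <- union_networks(list(a, b))
  expect_equal(nrow(u), 2L)

  a2 <- edge_tbl("a", "x", 0.2)
  b2 <- edge_tbl("a", "x", 0.5)
  c2 <- edge_tbl("a", "x", 0.35)
  u_max <- union_networks(list(a2, b2, c2), weight_rule = "max")
  expect_equal(u_max$weight, 0.5)
  u_mean <- union_networks(list(a2, b2, c2), weight_rule = "mean")
  expect_equal(u_mean$weight, mean(c(0.2, 0.5, 0.35)))
  expect_error(union_networks(list(a)), "at least 2")
})

test_that("union cardinality matches inclusion-exclusion set enumeration", {
  set.seed(21)
  make_list <- function(seed) {
    set.seed(seed)
    pairs <- expand.grid(regulator = paste0("TF", 1:12),
                         target = paste0("G", 1:40),
                         stringsAsFactors = FALSE)
    pick <- pairs[sample(nrow(pairs), 100), ]
    edge_tbl(pick$regulator, pick$target, stats::runif(100))
  }
  lists <- lapply(1:6, make_list)
  u <- union_networks(lists)
  key_sets <- lapply(lists, function(e) unique(paste(e$regulator, e$target)))
  expect_equal(nrow(u), length(Reduce(union, key_sets)))
  # provenance flags: each pair flagged for exactly the lists containing it
  flags <- as.matrix(u[, grepl("^in_", names(u))])
  member <- sapply(key_sets, function(s) paste(u$regulator, u$target) %in% s)
  expect_equal(unname(flags), unname(member))
  # containment invariants
  for (e in lists) {
    expect_true(all(paste(e$regulator, e$target) %in%
                      paste(u$regulator, u$target)))
  }
  expect_lte(nrow(u), sum(vapply(lists, nrow, integer(1))))
})

test_that("intersection keeps pairs present in every input", {
  a <- edge_tbl(c("a", "b", "c"), c("x", "y", "z"), c(0.9, 0.5, 0.1))
  b <- edge_tbl(c("a", "b", "d"), c("x", "y", "w"), c(0.3, 0.7, 0.2))
  c_ <- edge_tbl(c("a", "b"), c("x", "y"), c(0.6, 0.6))
  i <- intersect_networks(list(a, b, c_))
  expect_setequal(paste(i$regulator, i$target), c("a x", "b y"))
  expect_equal(i$weight[i$regulator == "a"], mean(c(0.9, 0.3, 0.6)))

  ident <- intersect_networks(list(a, a))
  expect_setequal(paste(ident$regulator, ident$target),
                  paste(a$regulator, a$target))

  disj <- edge_tbl("q", "r", 0.5)
  expect_message(empty <- intersect_networks(list(a, disj)), "no edges")
  expect_equal(nrow(empty), 0L)
})

test_that("high-confidence network follows the intersect-then-union rule", {
  mk <- function(pairs, w = 0.5) {
    edge_tbl(sub(" .*", "", pairs), sub(".* ", "", pairs),
             rep(w, length(pairs)))
  }
  mean_suite <- list(mm = mk(c("a x", "a y", "b z")),
                     TT = mk(c("a x", "a y", "c q")),
                     Tm = mk(c("a x", "a y", "d r")))
  bulked_suite <- list(mm = mk(c("a y", "e w", "f v")),
                       TT = mk(c("a y", "e w")),
                       Tm = mk(c("a y", "e w", "g u")))
  hc <- build_high_confidence(mean_suite, bulked_suite, top_k = 10)
  # mean intersection {a x, a y}; bulked intersection {a y, e w}
  expect_setequal(paste(hc$regulator, hc$target), c("a x", "a y", "e w"))
  expect_error(build_high_confidence(mean_suite[c("mm", "TT")], bulked_suite),
               "mm")
})

test_that("high-confidence is contained in the union of the same six lists", {
  atlas <- small_atlas(seed = 12)
  rna_m <- atlas_layer(atlas, "rna", "mean")
  ribo_m <- atlas_layer(atlas, "ribo", "mean")
  rna_b <- atlas_layer(atlas, "rna", "bulked")
  ribo_b <- atlas_layer(atlas, "ribo", "bulked")
  regs <- head(atlas$truth$regulators, 6)
  tgts <- head(atlas$truth$targets, 25)
  suite <- function(rna, ribo, src) {
    list(mm = infer_grn(rna, rna, regs, tgts, "mm", src, n_trees = 20,
                        seed = 1),
         TT = infer_grn(ribo, ribo, regs, tgts, "TT", src, n_trees = 20,
                        seed = 1),
         Tm = infer_grn(ribo, rna, regs, tgts, "Tm", src, n_trees = 20,
                        seed = 1))
  }
  sm <- suite(rna_m, ribo_m, "mean")
  sb <- suite(rna_b, ribo_b, "bulked")
  top <- 60
  cut <- function(s) lapply(s, truncate_edges, mode = "top_k", value = top)
  u <- union_networks(c(cut(sm), cut(sb)))
  hc <- build_high_confidence(sm, sb, top_k = top)
  expect_true(all(paste(hc$regulator, hc$target) %in%
                    paste(u$regulator, u$target)))
})

test_that("topology metrics match hand-enumerated graphs", {
  tri <- edge_tbl(c("a", "b", "c"), c("b", "c", "a"), c(1, 1, 1))
  t1 <- topology_metrics(tri)
  expect_equal(t1$transitivity, 1)
  expect_equal(t1$average_path_length, 1)

  path <- edge_tbl(c("a", "b"), c("b", "c"), c(1, 1))
  t2 <- topology_metrics(path)
  expect_equal(t2$transitivity, 0)
  expect_equal(t2$average_path_length, 4 / 3)

  cliq <- expand.grid(a = paste0("u", 1:5), b = paste0("u", 1:5),
                      stringsAsFactors = FALSE)
  cliq <- cliq[cliq$a < cliq$b, ]
  cliq2 <- data.frame(a = sub("u", "v", cliq$a), b = sub("u", "v", cliq$b))
  both <- edge_tbl(c(cliq$a, cliq2$a), c(cliq$b, cliq2$b),
                   rep(1, 2 * nrow(cliq)))
  t3 <- topology_metrics(both, min_nodes = 5)
  expect_equal(t3$module_count, 2L)
  expect_error(topology_metrics(both[0, ]), "empty")
})

test_that("topology metrics agree with brute force on random small graphs", {
  set.seed(33)
  for (case in 1:100) {
    n <- sample(3:8, 1)
    adj <- matrix(0L, n, n)
    upper <- which(upper.tri(adj))
    on <- upper[stats::runif(length(upper)) < 0.4]
    if (length(on) == 0) next
    adj[on] <- 1L
    adj <- adj + t(adj)
    idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    edges <- edge_tbl(paste0("n", idx[, 1]), paste0("n", idx[, 2]),
                      rep(1, nrow(idx)))
    got <- topology_metrics(edges, min_nodes = 3)
    # oracle works on the full vertex set; restrict to vertices with edges
    used <- sort(unique(c(idx[, 1], idx[, 2])))
    want <- oracle_topology(adj[used, used, drop = FALSE], min_nodes = 3)
    expect_equal(got$transitivity, want$transitivity, tolerance = 1e-12)
    expect_equal(got$average_path_length, want$average_path_length,
                 tolerance = 1e-12)
    expect_equal(got$module_count, want$module_count)
  }
})

test_that("sub-network extraction filters and is idempotent", {
  e <- edge_tbl(rep(c("a", "b", "c"), each = 3),
                paste0("t", 1:9), seq(0.9, 0.1, by = -0.1))
  all_regs <- unique(e$regulator)
  expect_identical(extract_subnetwork(e, regulators = all_regs), e)
  sub <- extract_subnetwork(e, regulators = c("a", "b"))
  expect_equal(nrow(sub), 6L)
  expect_identical(extract_subnetwork(sub, regulators = c("a", "b")), sub)
  expect_warning(none <- extract_subnetwork(e, min_weight = 2), "no edges")
  expect_equal(nrow(none), 0L)
  stringent <- extract_subnetwork(e, min_weight = 0.5)
  expect_true(all(stringent$weight >= 0.5))
})

test_that("tissue-specific sub-network recovers a planted pair", {
  samples <- c("l1", "l2", "r1", "r2")
  meta <- tibble::tibble(sample_id = samples,
                         tissue_category = c("leaf", "leaf", "root", "root"),
                         source = "mean")
  # TFleaf translated only in leaf; Gleaf expressed only in leaf;
  # TFroot/Ground the mirror image; Gubiq everywhere.
  rna_v <- matrix(c(5, 4, 0, 0,
                    0, 0, 5, 4,
                    6, 5, 0, 0,
                    0, 0, 6, 5,
                    3, 3, 3, 3),
                  nrow = 5, byrow = TRUE,
                  dimnames = list(c("TFleaf", "TFroot", "Gleaf", "Ground",
                                    "Gubiq"), samples))
  rna <- make_expr(rna_v)
  ribo <- make_expr(rna_v, omics = "translatome")
  seg <- detect_segs(rna, ribo, meta)
  grn <- edge_tbl(c("TFleaf", "TFleaf", "TFroot", "TFroot"),
                  c("Gleaf", "Gubiq", "Ground", "Gleaf"),
                  c(0.5, 0.4, 0.3, 0.2))
  leaf <- tissue_specific_subgrn(grn, seg, "leaf")
  expect_identical(paste(leaf$regulator, leaf$target), "TFleaf Gleaf")
  suppressWarnings(root <- tissue_specific_subgrn(grn, seg, "root"))
  expect_false("TFleaf Gleaf" %in% paste(root$regulator, root$target))
  expect_identical(paste(root$regulator, root$target), "TFroot Ground")
  expect_error(tissue_specific_subgrn(grn, seg, "petal"), "unknown")
})
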