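# Shared fixtures and independent oracles, built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wide expression tibble from a gene x sample matrix.
make_expr <- function(m, omics = "transcriptome", source = "mean") {
  expr_matrix(
    dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                     tibble::as_tibble(m, .name_repair = "minimal")),
    omics = omics, source = source
  )
}

rand_expr <- function(n_genes, n_samples, seed = 1, prefix = "g") {
  set.seed(seed)
  m <- matrix(round(stats::runif(n_genes * n_samples, 0, 10), 3),
              n_genes, n_samples,
              dimnames = list(paste0(prefix, seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  make_expr(m)
}

# Brute-force best-split oracle: per-regulator maximum variance reduction
# ((SS(y) - SS(left) - SS(right)) / n) over all midpoint thresholds.
oracle_best_split <- function(X, y) {
  n <- nrow(X)
  ss <- function(v) if (length(v) == 0) 0 else sum((v - mean(v))^2)
  vapply(seq_len(ncol(X)), function(j) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2) return(0)
    reds <- vapply(seq_len(length(xs) - 1), function(i) {
      th <- (xs[i] + xs[i + 1]) / 2
      (ss(y) - ss(y[X[, j] <= th]) - ss(y[X[, j] > th])) / n
    }, numeric(1))
    max(reds)
  }, numeric(1))
}

# All-pairs comparison oracle for AUROC (ties count 1/2).
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Brute-force topology oracle on an adjacency matrix (undirected simple).
oracle_topology <- function(adj, min_nodes = 5) {
  n <- nrow(adj)
  # transitivity: 3 * triangles / connected triples
  triangles <- 0
  triples <- 0
  if (n >= 3) {
    combs <- utils::combn(n, 3)
    for (i in seq_len(ncol(combs))) {
      v <- combs[, i]
      e <- adj[v[1], v[2]] + adj[v[1], v[3]] + adj[v[2], v[3]]
      if (e == 3) triangles <- triangles + 1
    }
  }
  for (v in seq_len(n)) {
    d <- sum(adj[v, ])
    triples <- triples + d * (d - 1) / 2
  }
  trans <- if (triples == 0) NA_real_ else 3 * triangles / triples
  # Floyd-Warshall shortest paths
  d <- ifelse(adj == 1, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  finite <- d[upper.tri(d)][is.finite(d[upper.tri(d)])]
  apl <- if (length(finite) == 0) NaN else mean(finite)
  # connected components via reachability
  comp_id <- integer(n)
  cid <- 0
  for (v in seq_len(n)) {
    if (comp_id[v] == 0) {
      cid <- cid + 1
      comp_id[is.finite(d[v, ])] <- cid
    }
  }
  sizes <- table(comp_id)
  list(transitivity = trans, average_path_length = apl,
       module_count = sum(sizes >= min_nodes))
}

# Minimal edge-list tibble from regulator/target/weight vectors.
edge_tbl <- function(regulator, target, weight,
                     grn_type = NULL, source = NULL) {
  e <- tibble::tibble(regulator = regulator, target = target,
                      weight = weight)
  if (!is.null(grn_type)) e$grn_type <- grn_type
  if (!is.null(source)) e$source <- source
  omixgrn:::rank_edge_list(e)
}

# Small default atlas reused across tests.
small_atlas <- function(seed = 1, te_sigma = 1, noise_sd = 0.25,
                        dropout = 0.02, n_tf = 10, n_target = 60,
                        n_tissues = 9) {
  truth <- generate_truth_network(n_tf, n_target, mean_out_degree = 6,
                                  seed = seed)
  simulate_atlas(truth, n_tissues = n_tissues,
                 categories = c("root", "leaf", "kernel"),
                 te_sigma = te_sigma, noise_sd = noise_sd,
                 detection_dropout = dropout, seed = seed)
}
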