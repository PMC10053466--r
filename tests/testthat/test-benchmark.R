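gold_fix <- function() {
  gold_standard(
    tibble::tibble(tf = c("T1", "T1", "T2"), target = c("g2", "g3", "g1")),
    tf_universe = c("T1", "T2"),
    target_universe = paste0("g", 1:10)
  )
}

test_that("gold overlap counts shared pairs over shared TFs", {
  grn <- edge_tbl(c("T1", "T1"), c("g1", "g2"), c(0.8, 0.6))
  ov <- overlap_gold(grn, gold_fix())
  expect_equal(ov$total, 1L)  # only (T1, g2)
  expect_equal(ov$per_tf$overlap[ov$per_tf$tf == "T1"], 1L)

  same <- edge_tbl(c("T1", "T1", "T2"), c("g2", "g3", "g1"), c(1, 1, 1))
  expect_equal(overlap_gold(same, gold_fix())$total, 3L)

  none <- edge_tbl("TX", "g1", 1)
  expect_error(overlap_gold(none, gold_fix()), "shared TFs")
})

test_that("overlap equals direct set intersection on random networks", {
  set.seed(17)
  gold_edges <- tibble::tibble(
    tf = sample(paste0("T", 1:8), 50, replace = TRUE),
    target = sample(paste0("g", 1:60), 50, replace = TRUE)
  ) |> dplyr::distinct()
  gold <- gold_standard(gold_edges, paste0("T", 1:8), paste0("g", 1:60))
  grn_pairs <- tibble::tibble(
    regulator = sample(paste0("T", 1:8), 100, replace = TRUE),
    target = sample(paste0("g", 1:60), 100, replace = TRUE)
  ) |> dplyr::distinct()
  grn <- edge_tbl(grn_pairs$regulator, grn_pairs$target,
                  stats::runif(nrow(grn_pairs)))
  ov <- overlap_gold(grn, gold)
  want <- length(intersect(paste(grn$regulator, grn$target),
                           paste(gold$edges$tf, gold$edges$target)))
  expect_equal(ov$total, want)
  expect_true(all(ov$per_tf$overlap <=
                    pmin(ov$per_tf$grn_targets, ov$per_tf$gold_targets)))
})

test_that("randomized null has the analytic hypergeometric mean", {
  # single TF with k network targets, m gold targets, universe N
  N <- 40; k <- 12; m <- 8
  universe <- paste0("g", 1:N)
  gold <- gold_standard(tibble::tibble(tf = "T1", target = universe[1:m]),
                        "T1", universe)
  grn <- edge_tbl(rep("T1", k), universe[10 + seq_len(k)], stats::runif(k))
  null <- random_overlap_null(grn, gold, n_iter = 1000, seed = 2)
  pool <- N  # TF id not in the target universe here
  expected <- k * m / pool
  v <- stats::var(null$values)
  se <- sqrt(v / null$n_iter)
  expect_lt(abs(null$mean - expected), 3 * se + 1e-9)
  expect_equal(null$per_tf_expected$expected, expected)
})

test_that("degenerate nulls hit their forced values", {
  universe <- paste0("g", 1:10)
  grn <- edge_tbl(rep("T1", 4), universe[1:4], stats::runif(4))
  all_gold <- gold_standard(tibble::tibble(tf = "T1", target = universe),
                            "T1", universe)
  null <- random_overlap_null(grn, all_gold, n_iter = 50, seed = 1)
  expect_true(all(null$values == 4))

  # TF requesting more targets than the universe holds
  tiny <- gold_standard(tibble::tibble(tf = "T1", target = "g1"),
                        "T1", paste0("g", 1:3))
  big <- edge_tbl(rep("T1", 5), paste0("g", 1:5), stats::runif(5))
  expect_error(random_overlap_null(big, tiny, n_iter = 5, seed = 1),
               "universe")
})

test_that("chi-square overlap test matches the closed form", {
  expect_equal(chisq_overlap(30, 30, 100)$chi2, 0)
  expect_equal(chisq_overlap(30, 30, 100)$p, 1)

  res <- chisq_overlap(30, 10, 100)
  tab <- rbind(c(30, 70), c(10, 90))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  want <- sum((tab - expected)^2 / expected)
  expect_equal(res$chi2, want, tolerance = 1e-10)
  expect_equal(res$p, stats::pchisq(want, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)

  masked <- chisq_overlap(0, 0, 100)
  expect_true(masked$masked)
  expect_error(chisq_overlap(30, 10, 20), "n_pairs")
})

test_that("per-TF normalization divides by the right denominator", {
  grn <- edge_tbl(rep("T1", 10), paste0("g", 1:10), stats::runif(10))
  gold <- gold_standard(
    tibble::tibble(tf = "T1", target = c(paste0("g", 1:4), paste0("h", 1:4))),
    "T1", c(paste0("g", 1:10), paste0("h", 1:4)))
  raw <- per_tf_overlap_table(grn, gold, "none")
  expect_equal(raw$value, 4)
  by_grn <- per_tf_overlap_table(grn, gold, "grn_size")
  expect_equal(by_grn$value, 0.4)
  by_gold <- per_tf_overlap_table(grn, gold, "gold_size")
  expect_equal(by_gold$value, 0.5)
})

test_that("AUROC/AUPR reach their boundary values on separable rankings", {
  universe <- paste0("g", 1:20)
  gold <- gold_standard(tibble::tibble(tf = "T1", target = universe[1:5]),
                        "T1", universe)
  perfect <- edge_tbl(rep("T1", 20), universe, c(seq(1, 0.9, length.out = 5),
                                                 seq(0.5, 0.1,
                                                     length.out = 15)))
  r <- roc_pr_scores(perfect, gold)
  expect_equal(r$auroc, 1)
  expect_equal(r$aupr, 1)

  worst <- edge_tbl(rep("T1", 20), universe, c(seq(0.2, 0.1, length.out = 5),
                                               seq(1, 0.5,
                                                   length.out = 15)))
  expect_equal(roc_pr_scores(worst, gold)$auroc, 0)
})

test_that("rank-sum AUROC equals the all-pairs oracle, and reversals sum to 1", {
  set.seed(55)
  for (case in 1:100) {
    n <- sample(5:50, 1)
    n_pos <- sample(1:(n - 1), 1)
    scores <- round(stats::runif(n), sample(c(1, 2, 6), 1))  # induce ties
    labels <- c(rep(TRUE, n_pos), rep(FALSE, n - n_pos))[sample(n)]
    got <- omixgrn:::auroc_ranksum(scores, labels)
    expect_equal(got, oracle_auroc(scores, labels), tolerance = 1e-12)
  }
  # reversal identity without ties
  scores <- sample(seq(0.01, 0.99, length.out = 30))
  labels <- rep(c(TRUE, FALSE), 15)
  a <- omixgrn:::auroc_ranksum(scores, labels)
  b <- omixgrn:::auroc_ranksum(-scores, labels)
  expect_equal(a + b, 1)
})

test_that("TFs without positives or negatives are excluded per TF", {
  universe <- paste0("g", 1:6)
  gold <- gold_standard(
    tibble::tibble(tf = c("T1", "T2", "T2"), target = c("g1", "g2", "g3")),
    c("T1", "T2"), universe)
  gold$edges <- dplyr::bind_rows(
    gold$edges[gold$edges$tf == "T2", ],
    tibble::tibble(tf = "T1", target = universe))  # T1 has no negatives
  grn <- edge_tbl(rep(c("T1", "T2"), each = 3), rep(paste0("g", 1:3), 2),
                  stats::runif(6))
  r <- roc_pr_scores(grn, gold)
  expect_false(r$per_tf$included[r$per_tf$tf == "T1"])
  expect_true(r$per_tf$included[r$per_tf$tf == "T2"])
})

test_that("weight comparison reproduces the closed-form paired t", {
  mk <- function(w) edge_tbl(rep("a", 5), paste0("t", 1:5), w)
  x <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  y <- c(0.85, 0.82, 0.6, 0.55, 0.52)
  suites <- list(mm = mk(y), TT = mk(x), Tm = mk(x))
  res <- compare_weights(suites, thresholds = 5)
  d <- x - y
  t_hand <- mean(d) / (stats::sd(d) / sqrt(5))
  row <- res[res$comparison == "Tm_vs_mm", ]
  expect_equal(row$t, t_hand, tolerance = 1e-10)
  expect_equal(row$p, 2 * stats::pt(-abs(t_hand), 4), tolerance = 1e-12)
  # cross-check against the standard implementation
  tt <- stats::t.test(x, y, paired = TRUE)
  expect_equal(row$t, unname(tt$statistic))
  expect_equal(row$p, tt$p.value)

  # identical vectors: t = 0, p = 1
  same <- compare_weights(list(mm = mk(x), TT = mk(x), Tm = mk(x)),
                          thresholds = 5)
  expect_true(all(same$t == 0))
  expect_true(all(same$p == 1))

  # constant nonzero shift: zero variance of differences, masked
  shift <- compare_weights(list(mm = mk(x), TT = mk(x + 0.01),
                                Tm = mk(x)), thresholds = 5)
  row2 <- shift[shift$comparison == "TT_vs_mm", ]
  expect_true(row2$masked)
  expect_match(row2$reason, "zero variance")
})
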