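gold_sets <- function(gold) split(gold$edges$target, gold$edges$tf)

grn_sets <- function(edges, tfs = NULL) {
  e <- edges
  if (!is.null(tfs)) e <- e[e$regulator %in% tfs, , drop = FALSE]
  split(e$target, e$regulator)
}

#' Overlap between a network and a gold standard
#'
#' Counts (TF, target) pairs shared by the network and the gold standard,
#' restricted to TFs present in both.
#'
#' @param edges Edge-list tibble.
#' @param gold A `gold_standard`.
#' @return A `grn_overlap`: list with `per_tf` (tibble `tf`, `grn_targets`,
#'   `gold_targets`, `overlap`), `total`, `n_pairs` (network pairs over the
#'   shared TFs) and `shared_tfs`.
#' @export
overlap_gold <- function(edges, gold) {
  stopifnot(inherits(gold, "gold_standard"))
  shared <- intersect(unique(edges$regulator), unique(gold$edges$tf))
  if (length(shared) == 0) abort("no shared TFs between network and gold.")
  gs <- gold_sets(gold)
  ns <- grn_sets(edges, shared)
  per_tf <- purrr::map_dfr(sort(shared), function(tf) {
    gt <- ns[[tf]] %||% character(0)
    ct <- gs[[tf]] %||% character(0)
    tibble::tibble(tf = tf, grn_targets = length(gt),
                   gold_targets = length(ct),
                   overlap = length(intersect(gt, ct)))
  })
  structure(
    list(per_tf = per_tf, total = sum(per_tf$overlap),
         n_pairs = sum(per_tf$grn_targets), shared_tfs = sort(shared)),
    class = "grn_overlap"
  )
}

#' @export
print.grn_overlap <- function(x, ...) {
  cat(sprintf("<grn_overlap> %d / %d network pairs overlap gold (%d TFs)\n",
              x$total, x$n_pairs, nrow(x$per_tf)))
  invisible(x)
}

#' Randomized null distribution of gold overlap
#'
#' Repeats `n_iter` times: for each shared TF, redraw the same number of
#' targets uniformly without replacement from the declared target universe
#' (minus the TF itself) and count the overlap with the gold standard.
#' This is the random control network built from the same TF and target
#' sets as the real network.
#'
#' @inheritParams overlap_gold
#' @param n_iter Number of random networks (default 1000).
#' @param seed Integer seed.
#' @return An `overlap_null`: list with `values` (length `n_iter`), `mean`,
#'   `per_tf_expected` (analytic k*m/N expectation per TF), `n_iter`,
#'   `seed`.
#' @export
random_overlap_null <- function(edges, gold, n_iter = 1000, seed = 1) {
  stopifnot(inherits(gold, "gold_standard"))
  n_iter <- check_count(n_iter, "n_iter", min = 1L)
  ov <- overlap_gold(edges, gold)
  gs <- gold_sets(gold)
  universe <- gold$target_universe
  per_tf <- ov$per_tf
  draw_info <- purrr::map(seq_len(nrow(per_tf)), function(i) {
    tf <- per_tf$tf[i]
    pool <- setdiff(universe, tf)
    k <- per_tf$grn_targets[i]
    if (k > length(pool)) {
      abort(sprintf("TF %s has %d network targets but the universe holds %d.",
                    tf, k, length(pool)))
    }
    gold_in_pool <- intersect(gs[[tf]] %||% character(0), pool)
    list(pool = pool, k = k, gold = gold_in_pool)
  })
  set.seed(seed_for(seed, "null"))
  values <- vapply(seq_len(n_iter), function(it) {
    sum(vapply(draw_info, function(d) {
      if (d$k == 0) return(0L)
      length(intersect(sample(d$pool, d$k), d$gold))
    }, integer(1)))
  }, integer(1))
  expected <- purrr::map_dbl(draw_info, function(d) {
    d$k * length(d$gold) / length(d$pool)
  })
  structure(
    list(values = values, mean = mean(values),
         per_tf_expected = tibble::tibble(tf = per_tf$tf,
                                          expected = expected),
         n_iter = n_iter, seed = as.integer(seed), observed = ov$total),
    class = "overlap_null"
  )
}

#' @export
print.overlap_null <- function(x, ...) {
  cat(sprintf(
    "<overlap_null> %d iterations: mean %.2f (observed %d)\n",
    x$n_iter, x$mean, x$observed))
  invisible(x)
}

#' Chi-square test of observed versus null overlap
#'
#' Builds the 2x2 contingency table (overlapping vs non-overlapping pairs,
#' observed vs expected-from-null) over the `n_pairs` network pairs
#' considered and tests it with a df = 1 chi-square without continuity
#' correction (upper-tail p). A zero expected cell masks the result with a
#' reason instead of failing.
#'
#' @param observed_overlap Observed overlapping-pair count.
#' @param null_mean_overlap Mean overlap of the randomized null.
#' @param n_pairs Total network pairs considered.
#' @return One-row tibble: `chi2`, `p`, `df`, `masked`, `reason`.
#' @export
chisq_overlap <- function(observed_overlap, null_mean_overlap, n_pairs) {
  check_scalar_number(observed_overlap, "observed_overlap", lower = 0)
  check_scalar_number(null_mean_overlap, "null_mean_overlap", lower = 0)
  check_scalar_number(n_pairs, "n_pairs", lower = 0)
  if (n_pairs < observed_overlap || n_pairs < null_mean_overlap) {
    abort("`n_pairs` must be >= both overlap values.")
  }
  tab <- rbind(observed = c(observed_overlap, n_pairs - observed_overlap),
               expected = c(null_mean_overlap, n_pairs - null_mean_overlap))
  expected_cells <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected_cells == 0)) {
    return(tibble::tibble(chi2 = NA_real_, p = NA_real_, df = 1L,
                          masked = TRUE, reason = "zero expected cell"))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(chi2 = unname(ht$statistic), p = unname(ht$p.value),
                 df = 1L, masked = FALSE, reason = NA_character_)
}

#' Per-TF overlap table with optional normalization
#'
#' Raw per-TF overlap counts, or overlaps normalized by each TF's network
#' target count (`"grn_size"`) or gold target count (`"gold_size"`).
#' Division by zero masks the per-TF entry.
#'
#' @inheritParams overlap_gold
#' @param normalization `"none"`, `"grn_size"` or `"gold_size"`.
#' @return Tibble: `tf`, `grn_targets`, `gold_targets`, `overlap`, `value`,
#'   `masked`.
#' @export
per_tf_overlap_table <- function(edges, gold,
                                 normalization = c("none", "grn_size",
                                                   "gold_size")) {
  normalization <- match.arg(normalization)
  per_tf <- overlap_gold(edges, gold)$per_tf
  denom <- switch(normalization,
    none = rep(1, nrow(per_tf)),
    grn_size = per_tf$grn_targets,
    gold_size = per_tf$gold_targets
  )
  per_tf$value <- ifelse(denom > 0, per_tf$overlap / denom, NA_real_)
  per_tf$masked <- denom == 0
  per_tf
}

# Midrank (Mann-Whitney) AUROC for a score vector and 0/1 labels.
auroc_ranksum <- function(scores, labels) {
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)  # midranks for ties
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Non-interpolated AUPR with tied scores processed as one group.
aupr_step <- function(scores, labels) {
  n_pos <- sum(labels)
  if (n_pos == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l)
  n_seen <- seq_along(l)
  last <- !duplicated(grp, fromLast = TRUE)  # last index of each tie group
  tp_g <- tp[last]
  n_g <- n_seen[last]
  prec <- tp_g / n_g
  rec <- tp_g / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' AUROC and AUPR against a gold standard
#'
#' For each TF, candidate targets are the declared target universe minus
#' the TF itself; positives are its gold targets; candidate pairs absent
#' from the network score 0. AUROC uses the rank-sum (Mann-Whitney)
#' formulation with midrank tie handling; AUPR uses stepwise,
#' non-interpolated precision-recall integration. With
#' `scope = "per_tf"`, TFs lacking a positive or a negative are excluded
#' from the average; with `scope = "pooled"` all (TF, candidate) pairs are
#' scored jointly.
#'
#' @inheritParams overlap_gold
#' @param scope `"per_tf"` or `"pooled"`.
#' @return A `roc_report`: list with `per_tf` (tibble `tf`, `n_pos`,
#'   `n_neg`, `auroc`, `aupr`, `included`), `auroc`, `aupr` (aggregate),
#'   `scope`.
#' @export
roc_pr_scores <- function(edges, gold, scope = c("per_tf", "pooled")) {
  scope <- match.arg(scope)
  stopifnot(inherits(gold, "gold_standard"))
  gs <- gold_sets(gold)
  tfs <- sort(names(gs))
  universe <- gold$target_universe
  weight_of <- setNames(edges$weight,
                        paste(edges$regulator, edges$target, sep = "\r"))
  pooled_scores <- list()
  pooled_labels <- list()
  per_tf <- purrr::map_dfr(tfs, function(tf) {
    cand <- setdiff(universe, tf)
    scores <- unname(weight_of[paste(tf, cand, sep = "\r")])
    scores[is.na(scores)] <- 0
    labels <- cand %in% gs[[tf]]
    pooled_scores[[tf]] <<- scores
    pooled_labels[[tf]] <<- labels
    tibble::tibble(
      tf = tf, n_pos = sum(labels), n_neg = sum(!labels),
      auroc = auroc_ranksum(scores, labels),
      aupr = aupr_step(scores, labels),
      included = sum(labels) > 0 && sum(!labels) > 0
    )
  })
  if (scope == "per_tf") {
    inc <- per_tf$included
    agg_auroc <- mean(per_tf$auroc[inc])
    agg_aupr <- mean(per_tf$aupr[inc])
  } else {
    s <- unlist(pooled_scores, use.names = FALSE)
    l <- unlist(pooled_labels, use.names = FALSE)
    agg_auroc <- auroc_ranksum(s, l)
    agg_aupr <- aupr_step(s, l)
  }
  structure(list(per_tf = per_tf, auroc = agg_auroc, aupr = agg_aupr,
                 scope = scope),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("<roc_report> scope %s: AUROC %.3f, AUPR %.3f (%d TFs)\n",
              x$scope, x$auroc, x$aupr, nrow(x$per_tf)))
  invisible(x)
}

paired_t_row <- function(x, y, label, threshold) {
  d <- x - y
  n <- length(d)
  base <- tibble::tibble(threshold = threshold, comparison = label,
                         n_pairs = n, mean_diff = mean(d))
  if (n < 3) {
    return(dplyr::mutate(base, t = NA_real_, p = NA_real_, masked = TRUE,
                         reason = "fewer than 3 shared pairs"))
  }
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) {
      return(dplyr::mutate(base, t = 0, p = 1, masked = FALSE,
                           reason = NA_character_))
    }
    return(dplyr::mutate(base, t = NA_real_, p = NA_real_, masked = TRUE,
                         reason = "zero variance of differences"))
  }
  tstat <- mean(d) / (s / sqrt(n))
  dplyr::mutate(base, t = tstat, p = 2 * stats::pt(-abs(tstat), n - 1),
                masked = FALSE, reason = NA_character_)
}

#' Compare edge weights across network types
#'
#' At each truncation threshold, restricts every network type to its top-k
#' edges, takes the (regulator, target) pairs present in all three, and
#' compares the weight vectors pairwise (Tm vs mm, TT vs mm, Tm vs TT)
#' with a two-sided paired t test. Degenerate inputs (fewer than 3 shared
#' pairs, or zero variance of the paired differences with nonzero mean)
#' are masked with a reason; identical weight vectors give t = 0, p = 1.
#'
#' @param suites Named list with elements `mm`, `TT`, `Tm` (edge lists
#'   sharing regulator/target universes).
#' @param thresholds Top-k values to evaluate (defaults follow the
#'   0.2/0.6/1 million-edge ladder).
#' @return Tibble with one row per threshold and comparison.
#' @export
compare_weights <- function(suites, thresholds = c(2e5, 6e5, 1e6)) {
  if (!all(c("mm", "TT", "Tm") %in% names(suites))) {
    abort("`suites` must contain elements `mm`, `TT` and `Tm`.")
  }
  purrr::map_dfr(thresholds, function(th) {
    cut <- purrr::map(suites[c("mm", "TT", "Tm")], truncate_edges,
                      mode = "top_k", value = th)
    keyed <- purrr::map(cut, function(e) {
      setNames(e$weight, paste(e$regulator, e$target, sep = "\r"))
    })
    common <- Reduce(intersect, purrr::map(keyed, names))
    if (length(common) < 3) {
      return(tibble::tibble(
        threshold = th,
        comparison = c("Tm_vs_mm", "TT_vs_mm", "Tm_vs_TT"),
        n_pairs = length(common), mean_diff = NA_real_, t = NA_real_,
        p = NA_real_, masked = TRUE, reason = "fewer than 3 shared pairs"))
    }
    w <- purrr::map(keyed, ~ unname(.x[common]))
    dplyr::bind_rows(
      paired_t_row(w$Tm, w$mm, "Tm_vs_mm", th),
      paired_t_row(w$TT, w$mm, "TT_vs_mm", th),
      paired_t_row(w$Tm, w$TT, "Tm_vs_TT", th)
    )
  })
}
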