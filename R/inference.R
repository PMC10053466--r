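#' Tree-ensemble importance of regulators for one target
#'
#' Fits an ensemble of `n_trees` regression trees predicting the target
#' expression profile from the regulator profiles across samples. At each
#' node a random subset of `k` candidate regulators is drawn and the split
#' with the largest variance (sum-of-squares) reduction is taken; a
#' regulator's raw importance is the total per-sample variance reduction
#' credited to its splits, averaged over trees. Importances are then
#' normalized to sum to 1 across regulators, so an edge weight is the share
#' of the target's explainable variance attributed to that regulator. A
#' constant target profile yields an all-zero importance vector (flagged
#' via the `constant_target` attribute), not an error.
#'
#' @param target_profile Numeric vector of target abundances over samples.
#' @param regulators Expression-matrix tibble restricted to the candidate
#'   regulators (rows), with the same ordered samples as `target_profile`.
#' @param n_trees Number of trees in the ensemble.
#' @param k Candidate regulators drawn per split: `"sqrt"` (ceiling of the
#'   square root of the regulator count), `"all"`, or a positive integer.
#' @param seed Integer seed; results are fully deterministic given the seed.
#' @param max_depth Maximum tree depth (0 = grow until pure); depth 1 fits
#'   single-split stumps.
#' @param bootstrap Draw a bootstrap sample of the tissues per tree
#'   (bagging); set `FALSE` to fit every tree on the full sample.
#' @return Tibble with `regulator`, `importance` (normalized weight) and
#'   `raw_importance` (per-sample variance reduction); attribute
#'   `constant_target` flags the degenerate case.
#' @export
rank_regulators_for_target <- function(target_profile, regulators,
                                       n_trees = 1000, k = "sqrt",
                                       seed = 1, max_depth = 0L,
                                       bootstrap = TRUE) {
  vals <- expr_values(regulators)
  n_samples <- ncol(vals)
  if (length(target_profile) != n_samples) {
    abort("`target_profile` length must match the number of samples.")
  }
  if (n_samples < 3) abort("at least 3 samples are required.")
  n_trees <- check_count(n_trees, "n_trees", min = 1L)
  mtry <- resolve_mtry(k, nrow(vals))

  reg_ids <- rownames(vals)
  if (stats::sd(target_profile) == 0) {
    out <- tibble::tibble(regulator = reg_ids, importance = 0,
                          raw_importance = 0)
    attr(out, "constant_target") <- TRUE
    return(out)
  }
  raw <- .forest_importance_cpp(t(vals), as.numeric(target_profile),
                                n_trees, mtry, as.integer(max_depth),
                                isTRUE(bootstrap), as.integer(seed))
  total <- sum(raw)
  imp <- if (total > 0) raw / total else raw
  out <- tibble::tibble(regulator = reg_ids, importance = imp,
                        raw_importance = raw)
  attr(out, "constant_target") <- FALSE
  out
}

resolve_mtry <- function(k, p) {
  if (identical(k, "sqrt")) return(max(1L, as.integer(ceiling(sqrt(p)))))
  if (identical(k, "all")) return(as.integer(p))
  k <- check_count(k, "k", min = 1L)
  min(k, as.integer(p))
}

#' Infer a weighted regulatory network
#'
#' Runs [rank_regulators_for_target()] for every target gene, using
#' regulator profiles from `regulator_matrix` and the target profile from
#' `target_matrix`. When the two matrices come from different omics layers
#' this yields an inter-omics network (e.g. TF translatome driving target
#' transcriptome, type `"Tm"`); same-layer pairings give the intra-omics
#' `"mm"` and `"TT"` networks. A TF appearing among the targets never
#' serves as its own regulator, so the result contains no self-edges.
#' Edges are ranked globally by weight with the deterministic tie-break
#' (weight descending, regulator id ascending, target id ascending).
#'
#' Per-target seeds are derived from `seed` and the target id only, so
#' runs over different matrices (e.g. the three network types on a
#' collapsed atlas) use identical randomization per target.
#'
#' @param regulator_matrix,target_matrix Expression matrices sharing an
#'   identical ordered sample set.
#' @param regulator_ids,target_ids Gene ids (already filtered, e.g. by
#'   [select_regulators()] / [filter_grn_genes()]).
#' @param grn_type Network type label: `"mm"`, `"TT"` or `"Tm"`.
#' @param source Data source label: `"mean"` or `"bulked"`.
#' @param log_transform Apply `log1p` to abundances before fitting
#'   (off by default; raw FPKM scale is used).
#' @inheritParams rank_regulators_for_target
#' @return An edge-list tibble: `regulator`, `target`, `weight`, `rank`,
#'   `grn_type`, `source`; attribute `params` records the fingerprint
#'   (trees, k, seed, sample and gene counts).
#' @export
infer_grn <- function(regulator_matrix, target_matrix, regulator_ids,
                      target_ids, grn_type = c("mm", "TT", "Tm"),
                      source = c("mean", "bulked"), n_trees = 1000,
                      k = "sqrt", seed = 1, log_transform = FALSE) {
  grn_type <- match.arg(grn_type)
  source <- match.arg(source)
  if (!identical(expr_samples(regulator_matrix),
                 expr_samples(target_matrix))) {
    abort(paste("regulator and target matrices must share the identical",
                "ordered sample set (inter-omics inference requires",
                "tissue-matched layers)."))
  }
  if (length(regulator_ids) == 0) abort("`regulator_ids` must be nonempty.")
  if (length(target_ids) == 0) abort("`target_ids` must be nonempty.")
  missing_r <- setdiff(regulator_ids, expr_genes(regulator_matrix))
  if (length(missing_r)) abort("regulator ids absent from regulator_matrix.")
  missing_t <- setdiff(target_ids, expr_genes(target_matrix))
  if (length(missing_t)) abort("target ids absent from target_matrix.")

  rv <- expr_values(regulator_matrix)[regulator_ids, , drop = FALSE]
  tv <- expr_values(target_matrix)[target_ids, , drop = FALSE]
  if (log_transform) {
    rv <- log1p(rv)
    tv <- log1p(tv)
  }
  xt <- t(rv)  # samples x regulators

  edges <- purrr::map_dfr(target_ids, function(tg) {
    keep <- regulator_ids != tg
    if (!any(keep)) return(NULL)
    x <- xt[, keep, drop = FALSE]
    y <- tv[tg, ]
    tgt_seed <- seed_for(seed, paste0("target:", tg))
    if (stats::sd(y) == 0) {
      imp <- rep(0, ncol(x))
    } else {
      raw <- .forest_importance_cpp(x, y, n_trees,
                                    resolve_mtry(k, ncol(x)), 0L, TRUE,
                                    tgt_seed)
      s <- sum(raw)
      imp <- if (s > 0) raw / s else raw
    }
    tibble::tibble(regulator = regulator_ids[keep], target = tg,
                   weight = imp)
  })
  edges <- rank_edge_list(edges)
  edges$grn_type <- grn_type
  edges$source <- source
  attr(edges, "params") <- list(
    n_trees = n_trees, k = k, seed = as.integer(seed),
    log_transform = log_transform,
    n_regulators = length(regulator_ids), n_targets = length(target_ids),
    n_samples = ncol(rv)
  )
  edges
}

# Deterministic global ranking: weight desc, regulator asc, target asc.
rank_edge_list <- function(edges) {
  edges <- dplyr::arrange(edges, dplyr::desc(.data$weight),
                          .data$regulator, .data$target)
  edges$rank <- seq_len(nrow(edges))
  edges
}

#' Truncate an edge list
#'
#' Keeps the top `value` ranks (`mode = "top_k"`, under the deterministic
#' tie-break) or all edges with weight at or above `value`
#' (`mode = "min_weight"`, inclusive threshold). The result is re-ranked
#' 1..N.
#'
#' @param edges An edge-list tibble (ranked).
#' @param mode `"top_k"` or `"min_weight"`.
#' @param value Rank cutoff or weight threshold (> 0).
#' @return The truncated, re-ranked edge list.
#' @export
truncate_edges <- function(edges, mode = c("top_k", "min_weight"), value) {
  mode <- match.arg(mode)
  check_scalar_number(value, "value", lower = 0, strict_lower = TRUE)
  out <- rank_edge_list(edges)
  if (mode == "top_k") {
    out <- out[out$rank <= floor(value), , drop = FALSE]
  } else {
    out <- out[out$weight >= value, , drop = FALSE]
  }
  rank_edge_list(out)
}

#' Read/write edge-list TSVs
#'
#' Columns: `regulator`, `target`, `weight` (full-precision), `rank`,
#' `grn_type`, `source`, plus any provenance flags from merges.
#'
#' @param path File path.
#' @param edges Edge-list tibble.
#' @return `read_edges()` returns a tibble; `write_edges()` returns `path`
#'   invisibly.
#' @export
read_edges <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_edges
#' @export
write_edges <- function(edges, path) {
  readr::write_tsv(edges, path, progress = FALSE)
  invisible(path)
}
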