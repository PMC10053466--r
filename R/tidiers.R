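# broom-style accessors for the package's result objects.

#' @exportS3Method
tidy.grn_truth <- function(x, ...) x$edges

#' @exportS3Method
glance.grn_truth <- function(x, ...) {
  tibble::tibble(
    n_tf = length(x$regulators), n_target = length(x$targets),
    n_edges = nrow(x$edges),
    realized_mean_out_degree = nrow(x$edges) / length(x$regulators),
    seed = x$seed
  )
}

#' @exportS3Method
tidy.gold_standard <- function(x, ...) x$edges

#' @exportS3Method
glance.gold_standard <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$edges),
                 n_tfs = length(unique(x$edges$tf)),
                 n_tf_universe = length(x$tf_universe),
                 n_target_universe = length(x$target_universe))
}

#' @exportS3Method
tidy.grn_overlap <- function(x, ...) x$per_tf

#' @exportS3Method
glance.grn_overlap <- function(x, ...) {
  tibble::tibble(total_overlap = x$total, n_pairs = x$n_pairs,
                 n_shared_tfs = length(x$shared_tfs))
}

#' @exportS3Method
tidy.overlap_null <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$values), overlap = x$values)
}

#' @exportS3Method
glance.overlap_null <- function(x, ...) {
  tibble::tibble(null_mean = x$mean, null_sd = stats::sd(x$values),
                 observed = x$observed, n_iter = x$n_iter, seed = x$seed)
}

#' @exportS3Method
tidy.roc_report <- function(x, ...) x$per_tf

#' @exportS3Method
glance.roc_report <- function(x, ...) {
  tibble::tibble(auroc = x$auroc, aupr = x$aupr, scope = x$scope,
                 n_tfs = sum(x$per_tf$included))
}

#' @exportS3Method
tidy.seg_report <- function(x, ...) x$genes

#' @exportS3Method
glance.seg_report <- function(x, ...) {
  tibble::tibble(n_categories = length(x$categories),
                 n_specific_genes = nrow(x$genes),
                 total_segs = sum(x$summary$seg_count))
}
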