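#' Plot a correlation report
#'
#' Histogram of Pearson's r across genes or sample pairs.
#'
#' @param cors Output of [correlation_report()].
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_correlations <- function(cors, bins = 30) {
  ggplot2::ggplot(cors[!cors$masked, ], ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "Pearson's r", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot edge-weight distributions of one or more networks
#'
#' @param edges Edge-list tibble (or row-bound tibble of several networks
#'   distinguished by `grn_type`).
#' @return A ggplot object.
#' @export
plot_weight_distribution <- function(edges) {
  mapping <- if ("grn_type" %in% names(edges)) {
    ggplot2::aes(x = .data$weight, colour = .data$grn_type)
  } else {
    ggplot2::aes(x = .data$weight)
  }
  ggplot2::ggplot(edges, mapping) +
    ggplot2::geom_density() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "edge weight", y = "density") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.seg_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$summary[, c("category", "transcribed", "translated", "both")],
    -"category", names_to = "specificity", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$n,
                                     fill = .data$specificity)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "specifically expressed genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @exportS3Method
autoplot.overlap_null <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(overlap = object$values),
                  ggplot2::aes(x = .data$overlap)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = "null overlap with gold standard", y = "count",
                  subtitle = sprintf("observed = %d, null mean = %.1f",
                                     object$observed, object$mean)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.roc_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_tf[object$per_tf$included, c("tf", "auroc", "aupr")],
    -"tf", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "per-TF value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
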