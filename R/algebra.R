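edge_label <- function(edges, default) {
  if (nrow(edges) > 0 && all(c("grn_type", "source") %in% names(edges))) {
    paste(edges$grn_type[1], edges$source[1], sep = "_")
  } else {
    default
  }
}

label_edge_lists <- function(lists) {
  if (!is.list(lists) || length(lists) < 2) {
    abort("at least 2 edge lists are required.")
  }
  labels <- names(lists)
  if (is.null(labels)) labels <- rep("", length(lists))
  for (i in seq_along(lists)) {
    if (labels[i] == "") labels[i] <- edge_label(lists[[i]], paste0("grn", i))
  }
  if (anyDuplicated(labels)) labels <- make.unique(labels, sep = "_")
  setNames(lists, labels)
}

#' Union of edge lists
#'
#' Deduplicated union on (regulator, target) pairs across two or more edge
#' lists (each typically truncated to its top edges beforehand). Weights of
#' pairs present in several inputs are aggregated with `weight_rule`;
#' per-input provenance flags (`in_<label>` logical columns, labels from
#' list names or `grn_type`/`source`) record which inputs contained each
#' pair.
#'
#' @param lists A list of >= 2 edge-list tibbles.
#' @param weight_rule `"max"` (default) or `"mean"`.
#' @return A re-ranked edge-list tibble with provenance columns.
#' @export
union_networks <- function(lists, weight_rule = c("max", "mean")) {
  weight_rule <- match.arg(weight_rule)
  lists <- label_edge_lists(lists)
  tagged <- purrr::imap(lists, function(e, lab) {
    tibble::tibble(regulator = e$regulator, target = e$target,
                   weight = e$weight, member = lab)
  })
  all_edges <- dplyr::bind_rows(tagged)
  agg <- all_edges |>
    dplyr::group_by(.data$regulator, .data$target) |>
    dplyr::summarise(
      weight = if (weight_rule == "max") max(.data$weight)
               else mean(.data$weight),
      members = list(unique(.data$member)),
      .groups = "drop"
    )
  for (lab in names(lists)) {
    agg[[paste0("in_", lab)]] <-
      purrr::map_lgl(agg$members, ~ lab %in% .x)
  }
  agg$members <- NULL
  rank_edge_list(agg)
}

#' Intersection of edge lists
#'
#' Pairs present in every input; the weight of a retained pair is the mean
#' of its member weights.
#'
#' @inheritParams union_networks
#' @return A re-ranked edge-list tibble (possibly empty, with a message).
#' @export
intersect_networks <- function(lists) {
  lists <- label_edge_lists(lists)
  pair_sets <- purrr::map(lists, ~ paste(.x$regulator, .x$target, sep = "\r"))
  common <- Reduce(intersect, pair_sets)
  all_edges <- dplyr::bind_rows(
    purrr::map(lists, ~ .x[, c("regulator", "target", "weight")])
  )
  key <- paste(all_edges$regulator, all_edges$target, sep = "\r")
  out <- all_edges[key %in% common, , drop = FALSE] |>
    dplyr::group_by(.data$regulator, .data$target) |>
    dplyr::summarise(weight = mean(.data$weight), .groups = "drop")
  if (nrow(out) == 0) {
    inform("intersect_networks: inputs share no edges; returning empty list.")
  }
  rank_edge_list(out)
}

#' High-confidence network from two data-source suites
#'
#' Intersects the three network types (mm, TT, Tm — each truncated to
#' `top_k` edges first) within each data source, then takes the union of
#' the two per-source intersections: an edge is high-confidence when all
#' three omics pairings agree on it in at least one data source.
#'
#' @param mean_suite,bulked_suite Named lists with elements `mm`, `TT`,
#'   `Tm` (edge-list tibbles).
#' @param top_k Truncation applied to each list before intersecting
#'   (default one million edges).
#' @param weight_rule Aggregation for the final union, see
#'   [union_networks()].
#' @return A re-ranked edge-list tibble with per-source provenance flags
#'   `in_mean`, `in_bulked`.
#' @export
build_high_confidence <- function(mean_suite, bulked_suite, top_k = 1e6,
                                  weight_rule = c("max", "mean")) {
  weight_rule <- match.arg(weight_rule)
  for (suite in list(mean_suite, bulked_suite)) {
    if (!all(c("mm", "TT", "Tm") %in% names(suite))) {
      abort("each suite must contain elements `mm`, `TT` and `Tm`.")
    }
  }
  cut <- function(suite) {
    purrr::map(suite[c("mm", "TT", "Tm")], truncate_edges,
               mode = "top_k", value = top_k)
  }
  per_source <- list(
    mean = intersect_networks(cut(mean_suite)),
    bulked = intersect_networks(cut(bulked_suite))
  )
  keep <- purrr::map_lgl(per_source, ~ nrow(.x) > 0)
  if (!any(keep)) {
    inform("build_high_confidence: no source-level intersection is nonempty.")
    out <- tibble::tibble(regulator = character(0), target = character(0),
                          weight = numeric(0), rank = integer(0),
                          in_mean = logical(0), in_bulked = logical(0))
    return(out)
  }
  if (sum(keep) == 1L) {
    out <- per_source[[which(keep)]]
    out$in_mean <- keep[["mean"]]
    out$in_bulked <- keep[["bulked"]]
    return(rank_edge_list(out))
  }
  union_networks(per_source, weight_rule = weight_rule)
}

#' Topology metrics of a network
#'
#' Computed on the undirected simple graph induced by the edges:
#' transitivity (global clustering coefficient, 3 x triangles over
#' connected triples), average shortest-path length over connected pairs
#' (disconnected pairs are ignored), and the number of modules, defined as
#' connected components with at least `min_nodes` nodes.
#'
#' @param edges Nonempty edge-list tibble.
#' @param min_nodes Minimum component size to count as a module.
#' @return One-row tibble: `n_nodes`, `n_edges`, `transitivity`,
#'   `average_path_length`, `module_count`, `min_nodes`.
#' @export
topology_metrics <- function(edges, min_nodes = 5) {
  if (nrow(edges) == 0) abort("edge list is empty.")
  g <- igraph::graph_from_data_frame(
    edges[, c("regulator", "target")], directed = FALSE)
  g <- igraph::simplify(g)
  trans <- igraph::transitivity(g, type = "global")
  if (is.nan(trans)) trans <- NA_real_
  apl <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  comp <- igraph::components(g)
  tibble::tibble(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    transitivity = trans,
    average_path_length = apl,
    module_count = sum(comp$csize >= min_nodes),
    min_nodes = as.integer(min_nodes)
  )
}

#' Extract a sub-network by regulator/target/weight filters
#'
#' @param edges Edge-list tibble.
#' @param regulators Optional regulator id set to keep.
#' @param targets Optional target id set to keep.
#' @param min_weight Optional inclusive weight threshold (e.g. 0.05 for a
#'   stringent TF-family sub-network).
#' @return The filtered, re-ranked edge list (warns when empty).
#' @export
extract_subnetwork <- function(edges, regulators = NULL, targets = NULL,
                               min_weight = NULL) {
  out <- edges
  if (!is.null(regulators)) out <- out[out$regulator %in% regulators, ]
  if (!is.null(targets)) out <- out[out$target %in% targets, ]
  if (!is.null(min_weight)) out <- out[out$weight >= min_weight, ]
  if (nrow(out) == 0) warn("extract_subnetwork: no edges pass the filters.")
  rank_edge_list(out)
}

#' Tissue-specific sub-network
#'
#' Keeps edges whose regulator is specifically translated in the given
#' tissue category and whose target is specifically expressed (at either
#' omics layer) in the same category — i.e. regulator and target are
#' simultaneously detected only in that tissue type.
#'
#' @param edges Edge-list tibble.
#' @param seg_report A `seg_report` from [detect_segs()].
#' @param category Tissue-category label covered by the report.
#' @return The filtered, re-ranked edge list.
#' @export
tissue_specific_subgrn <- function(edges, seg_report, category) {
  stopifnot(inherits(seg_report, "seg_report"))
  if (!category %in% seg_report$categories) {
    abort(sprintf("unknown tissue category '%s'.", category))
  }
  g <- seg_report$genes
  in_cat <- g[g$category == category, , drop = FALSE]
  reg_ok <- in_cat$gene_id[in_cat$specificity %in% c("translated", "both")]
  tgt_ok <- in_cat$gene_id
  extract_subnetwork(edges, regulators = reg_ok, targets = tgt_ok)
}
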