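pipeline_config_defaults <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    simulation = list(
      n_tf = 20L, n_target = 200L, mean_out_degree = 20,
      n_tissues = 12L, categories = default_tissue_categories(),
      te_sigma = 1, noise_sd = 0.25, detection_dropout = 0.02,
      specific_fraction = 0.05
    ),
    gold = list(observed_fraction = 0.8, spurious_fraction = 0.25),
    filters = list(fpkm_min = 1, min_nonzero = 3),
    inference = list(n_trees = 1000L, k = "sqrt", log_transform = FALSE),
    truncation = list(top_k = 1e6),
    benchmark = list(n_iter = 1000L, thresholds = c(2e5, 6e5, 1e6),
                     seed = NULL)
  )
}

#' Validate and resolve a pipeline configuration
#'
#' A configuration is a nested list (or path to a YAML file) with sections
#' `simulation`, `gold`, `filters`, `inference`, `truncation`, `benchmark`
#' plus top-level `seed` and `output_dir`. Unknown keys are rejected;
#' missing keys take the documented defaults. The fully resolved
#' configuration is serialized alongside the outputs of [run_pipeline()].
#'
#' @param config Nested list or YAML path.
#' @return The resolved configuration list.
#' @export
resolve_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- pipeline_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  out <- defaults
  for (section in names(config)) {
    if (is.list(defaults[[section]]) && !is.null(names(defaults[[section]]))) {
      bad <- setdiff(names(config[[section]]), names(defaults[[section]]))
      if (length(bad)) {
        abort(sprintf("unknown key(s) in `%s`: %s", section,
                      paste(bad, collapse = ", ")))
      }
      out[[section]][names(config[[section]])] <- config[[section]]
    } else {
      out[[section]] <- config[[section]]
    }
  }
  if (is.null(out$output_dir)) abort("`output_dir` must be set.")
  out$benchmark$seed <- out$benchmark$seed %||% seed_for(out$seed, "benchmark")
  out
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the full multi-omics GRN pipeline
#'
#' Orchestrates simulate -> QC -> inference (six networks: mm/TT/Tm for the
#' mean and bulked sources) -> truncation -> union and high-confidence
#' merging -> topology -> benchmarking, writing every artifact under
#' `output_dir` and returning a manifest with content hashes. Randomness is
#' split into named substreams (simulation, per-target inference,
#' benchmark null), so changing only `benchmark$seed` leaves all upstream
#' artifacts byte-identical.
#'
#' Within a data source the same regulator set (TFs passing the expression
#' filter in both omics layers) and the same target set (genes passing the
#' filter in the transcriptome) are used for all three network types, so
#' type-level comparisons are over identical pair universes.
#'
#' @param config Nested list or YAML path, see [resolve_config()].
#' @return A `pipeline_manifest`: list with `artifacts` (tibble `name`,
#'   `path`, `md5`), `config`, `config_fingerprint`, and `summary` (stage
#'   counts).
#' @export
run_pipeline <- function(config) {
  cfg <- resolve_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  summary <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  # --- simulate ---------------------------------------------------------
  sim <- cfg$simulation
  atlas <- stage("simulate", {
    truth <- generate_truth_network(sim$n_tf, sim$n_target,
                                    sim$mean_out_degree, seed = cfg$seed)
    simulate_atlas(truth, n_tissues = sim$n_tissues,
                   categories = sim$categories, te_sigma = sim$te_sigma,
                   noise_sd = sim$noise_sd,
                   detection_dropout = sim$detection_dropout,
                   specific_fraction = sim$specific_fraction,
                   seed = cfg$seed)
  })
  atlas_dir <- file.path(cfg$output_dir, "atlas")
  paths <- c(paths, stage("simulate", write_atlas(atlas, atlas_dir)))
  gold <- stage("simulate", make_gold_standard(
    atlas$truth, cfg$gold$observed_fraction, cfg$gold$spurious_fraction,
    seed = cfg$seed))
  paths["gold_standard"] <- file.path(cfg$output_dir, "gold_standard.tsv")
  write_gold_standard(gold, paths[["gold_standard"]])

  # --- qc ---------------------------------------------------------------
  layers <- stage("qc", {
    purrr::map(c(mean = "mean", bulked = "bulked"), function(src) {
      list(rna = atlas_layer(atlas, "rna", src),
           ribo = atlas_layer(atlas, "ribo", src))
    })
  })
  qc <- stage("qc", {
    purrr::imap(layers, function(ly, src) {
      regs <- select_regulators(atlas$truth$regulators, ly$rna, ly$ribo,
                                cfg$filters$fpkm_min, cfg$filters$min_nonzero)
      tgts <- intersect(
        filter_grn_genes(ly$rna, cfg$filters$fpkm_min,
                         cfg$filters$min_nonzero),
        atlas$truth$targets)
      list(regulators = regs, targets = tgts)
    })
  })
  seg <- stage("qc", detect_segs(layers$mean$rna, layers$mean$ribo,
                                 atlas$metadata))
  te <- stage("qc", compute_te(layers$mean$ribo, layers$mean$rna))
  cors <- stage("qc", correlation_report(layers$mean$rna, layers$mean$ribo,
                                         axis = "per_gene"))
  paths["seg_summary"] <- file.path(cfg$output_dir, "seg_summary.tsv")
  readr::write_tsv(seg$summary, paths[["seg_summary"]], progress = FALSE)
  paths["te_table"] <- file.path(cfg$output_dir, "te_table.tsv")
  readr::write_tsv(te, paths[["te_table"]], progress = FALSE)
  qc_report <- list(
    n_genes = nrow(atlas$matrices[[1]]),
    per_source = purrr::imap(qc, function(q, src) {
      list(n_regulators = length(q$regulators), n_targets = length(q$targets))
    }),
    median_cross_omics_r = stats::median(cors$r, na.rm = TRUE),
    te_unmasked_fraction = mean(!te$masked)
  )
  paths["qc_report"] <- file.path(cfg$output_dir, "qc_report.json")
  write_json_artifact(qc_report, paths[["qc_report"]])
  summary$qc <- qc_report

  # --- infer ------------------------------------------------------------
  infer_seed <- seed_for(cfg$seed, "infer")
  suites <- stage("infer", {
    purrr::imap(layers, function(ly, src) {
      regs <- qc[[src]]$regulators
      tgts <- qc[[src]]$targets
      list(
        mm = infer_grn(ly$rna, ly$rna, regs, tgts, "mm", src,
                       n_trees = cfg$inference$n_trees, k = cfg$inference$k,
                       seed = infer_seed,
                       log_transform = cfg$inference$log_transform),
        TT = infer_grn(ly$ribo, ly$ribo, regs, tgts, "TT", src,
                       n_trees = cfg$inference$n_trees, k = cfg$inference$k,
                       seed = infer_seed,
                       log_transform = cfg$inference$log_transform),
        Tm = infer_grn(ly$ribo, ly$rna, regs, tgts, "Tm", src,
                       n_trees = cfg$inference$n_trees, k = cfg$inference$k,
                       seed = infer_seed,
                       log_transform = cfg$inference$log_transform)
      )
    })
  })
  suites <- stage("truncate", {
    purrr::map(suites, function(s) {
      purrr::map(s, truncate_edges, mode = "top_k",
                 value = cfg$truncation$top_k)
    })
  })
  for (src in names(suites)) {
    for (tp in names(suites[[src]])) {
      nm <- paste0("grn_", tp, "_", src)
      paths[nm] <- file.path(cfg$output_dir, paste0(nm, ".tsv"))
      write_edges(suites[[src]][[tp]], paths[[nm]])
    }
  }

  # --- merge ------------------------------------------------------------
  all_six <- c(suites$mean, suites$bulked)
  names(all_six) <- paste0(rep(c("mm", "TT", "Tm"), 2), "_",
                           rep(c("mean", "bulked"), each = 3))
  union_grn <- stage("merge", union_networks(all_six))
  hc_grn <- stage("merge", build_high_confidence(suites$mean, suites$bulked,
                                                 top_k = cfg$truncation$top_k))
  paths["union_grn"] <- file.path(cfg$output_dir, "union_grn.tsv")
  write_edges(union_grn, paths[["union_grn"]])
  paths["high_confidence_grn"] <- file.path(cfg$output_dir,
                                            "high_confidence_grn.tsv")
  write_edges(hc_grn, paths[["high_confidence_grn"]])
  summary$merge <- list(union_pairs = nrow(union_grn),
                        high_confidence_pairs = nrow(hc_grn))

  # --- topology ---------------------------------------------------------
  topo <- stage("topology", {
    nets <- c(all_six, list(union = union_grn))
    if (nrow(hc_grn) > 0) nets$high_confidence <- hc_grn
    purrr::imap_dfr(nets, function(e, nm) {
      dplyr::mutate(topology_metrics(e), network = nm, .before = 1)
    })
  })
  paths["topology"] <- file.path(cfg$output_dir, "topology.tsv")
  readr::write_tsv(topo, paths[["topology"]], progress = FALSE)

  # --- benchmark --------------------------------------------------------
  bench <- stage("benchmark", {
    purrr::imap(all_six, function(e, nm) {
      ov <- overlap_gold(e, gold)
      null <- random_overlap_null(e, gold, n_iter = cfg$benchmark$n_iter,
                                  seed = cfg$benchmark$seed)
      chi <- chisq_overlap(ov$total, null$mean, ov$n_pairs)
      roc <- roc_pr_scores(e, gold, scope = "per_tf")
      list(network = nm, observed_overlap = ov$total, n_pairs = ov$n_pairs,
           null_mean = null$mean, chi2 = chi$chi2, p = chi$p,
           chi2_masked = chi$masked, auroc = roc$auroc, aupr = roc$aupr)
    })
  })
  bench_tbl <- purrr::map_dfr(bench, tibble::as_tibble)
  wt <- stage("benchmark", {
    purrr::imap_dfr(suites, function(s, src) {
      dplyr::mutate(compare_weights(s, thresholds = cfg$benchmark$thresholds),
                    source = src, .before = 1)
    })
  })
  paths["benchmark_report"] <- file.path(cfg$output_dir,
                                         "benchmark_report.tsv")
  readr::write_tsv(bench_tbl, paths[["benchmark_report"]], progress = FALSE)
  paths["weight_comparison"] <- file.path(cfg$output_dir,
                                          "weight_comparison.tsv")
  readr::write_tsv(wt, paths[["weight_comparison"]], progress = FALSE)
  paths["benchmark_json"] <- file.path(cfg$output_dir, "benchmark.json")
  write_json_artifact(bench, paths[["benchmark_json"]])
  summary$benchmark <- bench

  # --- manifest ---------------------------------------------------------
  paths["config"] <- file.path(cfg$output_dir, "config.json")
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA),
             paths[["config"]])
  # fingerprint over the semantic configuration (where outputs land is not
  # part of what was computed)
  cfg_semantic <- cfg[setdiff(names(cfg), "output_dir")]
  fingerprint <- substr(paste(
    tools::md5sum(local({
      f <- tempfile()
      writeLines(jsonlite::toJSON(cfg_semantic, auto_unbox = TRUE,
                                  digits = NA), f)
      f
    }))), 1, 32)
  artifacts <- tibble::tibble(
    name = names(paths),
    path = unname(paths),
    md5 = unname(tools::md5sum(unname(paths)))
  )
  manifest <- structure(
    list(artifacts = artifacts, config = cfg,
         config_fingerprint = unname(fingerprint),
         summary = summary),
    class = "pipeline_manifest"
  )
  write_json_artifact(
    list(config_fingerprint = manifest$config_fingerprint,
         artifacts = artifacts),
    file.path(cfg$output_dir, "manifest.json"))
  manifest
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat(sprintf("<pipeline_manifest> %d artifacts (config %s)\n",
              nrow(x$artifacts), substr(x$config_fingerprint, 1, 8)))
  print(x$artifacts[, c("name", "md5")])
  invisible(x)
}
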