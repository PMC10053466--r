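#' Generate a ground-truth regulatory network
#'
#' Draws a random transcription-factor (TF) to target-gene network with
#' heavy-tailed out-degrees: a few hub TFs regulate many targets while most
#' TFs regulate few. Out-degrees are proportional to lognormal weights and
#' rescaled so the expected edge count is `n_tf * mean_out_degree`. Each
#' edge carries a signed effect size (positive with probability 0.75,
#' magnitude uniform on \[0.5, 2\]) used by [simulate_atlas()] to drive
#' target transcription from TF translational abundance. Regulator and
#' target id namespaces are disjoint, so the network contains no self-edges
#' by construction.
#'
#' @param n_tf Number of TFs (>= 2).
#' @param n_target Number of target genes (>= `n_tf`).
#' @param mean_out_degree Expected number of targets per TF.
#' @param seed Integer seed; identical seed and parameters give identical
#'   networks.
#' @return An object of class `grn_truth`: a list with `regulators`,
#'   `targets`, `edges` (tibble `regulator`, `target`, `effect`), `seed`
#'   and `params`.
#' @examples
#' truth <- generate_truth_network(5, 20, mean_out_degree = 4, seed = 1)
#' glance(truth)
#' @export
generate_truth_network <- function(n_tf, n_target, mean_out_degree = 20,
                                   seed = 1) {
  n_tf <- check_count(n_tf, "n_tf", min = 2L)
  n_target <- check_count(n_target, "n_target", min = 1L)
  if (n_target < n_tf) abort("`n_target` must be >= `n_tf`.")
  check_scalar_number(mean_out_degree, "mean_out_degree", lower = 0,
                      strict_lower = TRUE)

  regulators <- sprintf("TF%03d", seq_len(n_tf))
  targets <- sprintf("G%05d", seq_len(n_target))

  set.seed(seed_for(seed, "truth"))
  w <- exp(stats::rnorm(n_tf, 0, 1))
  deg <- round(mean_out_degree * n_tf * w / sum(w))
  deg <- pmin(pmax(deg, 1L), n_target)

  edges <- purrr::map2_dfr(regulators, deg, function(tf, d) {
    tg <- sample(targets, d, replace = FALSE)
    eff <- ifelse(stats::runif(d) < 0.75, 1, -1) * stats::runif(d, 0.5, 2)
    tibble::tibble(regulator = tf, target = tg, effect = eff)
  })

  structure(
    list(
      regulators = regulators, targets = targets, edges = edges,
      seed = as.integer(seed),
      params = list(n_tf = n_tf, n_target = n_target,
                    mean_out_degree = mean_out_degree)
    ),
    class = "grn_truth"
  )
}

#' @export
print.grn_truth <- function(x, ...) {
  cat(sprintf("<grn_truth> %d TFs, %d targets, %d edges (seed %d)\n",
              length(x$regulators), length(x$targets), nrow(x$edges), x$seed))
  invisible(x)
}

default_tissue_categories <- function() {
  c("root", "inflorescence", "stem", "seedling", "kernel",
    "tassel", "SAM", "ear", "leaf")
}

#' Simulate a paired transcriptome/translatome expression atlas
#'
#' Generates FPKM-scale gene-by-sample matrices for two omics layers
#' (RNA-seq transcriptome, Ribo-seq translatome) and three observed sources
#' (two replicates and a bulked sample per tissue), from a known regulatory
#' network. The generative model is:
#'
#' 1. TF mRNA abundance per tissue is lognormal (gene baseline + tissue
#'    effect + gene-by-tissue variation).
#' 2. Translational efficiency (TE) is drawn i.i.d. per gene and tissue on
#'    the log scale, `log TE ~ Normal(0, te_sigma)`, clipped so realized TE
#'    lies in `te_range` (default \[0.25, 4\]); TF translatome = TF mRNA
#'    times TE.
#' 3. Target transcriptome is a softplus of a linear combination of its
#'    regulators' standardized log-translatome profiles (effect sizes from
#'    the truth network) plus `Normal(0, noise_sd)` noise, scaled to an
#'    FPKM-like range — i.e. TF translational abundance, not TF mRNA,
#'    drives target transcription.
#' 4. Target translatome = target mRNA times the target's own TE.
#' 5. Replicates observe the latent signal with independent lognormal noise
#'    of log-scale sd `noise_sd`; the bulked source is the mean of three
#'    hidden replicates.
#' 6. A fraction of genes is tissue-category specific (zero outside one
#'    category), and each entry drops to zero with probability
#'    `detection_dropout`.
#'
#' @param truth A `grn_truth` from [generate_truth_network()].
#' @param n_tissues Number of tissues (default 21, the size of the
#'   replicated atlas design).
#' @param categories Tissue-category labels, assigned to tissues cyclically.
#' @param te_sigma Log-scale sd of translational efficiency (>= 0); 0 makes
#'   the two omics layers coincide exactly.
#' @param noise_sd Log-scale sd of replicate/observation noise (>= 0).
#' @param detection_dropout Per-entry dropout probability in \[0, 1).
#' @param specific_fraction Fraction of genes expressed in a single tissue
#'   category only.
#' @param te_range Clipping range for realized TE.
#' @param fpkm_scale Multiplicative constant mapping softplus output to an
#'   FPKM-like range.
#' @param seed Integer seed.
#' @return An object of class `grn_atlas`: list with `matrices` (named list
#'   `rna_rep1`, `rna_rep2`, `ribo_rep1`, `ribo_rep2`, `rna_bulked`,
#'   `ribo_bulked` of expression-matrix tibbles), `metadata` (sample_id,
#'   tissue_category, source; covers rep1/rep2/bulked/mean), `te_profile`
#'   (gene-by-tissue TE tibble), `truth`, and `params`.
#' @examples
#' truth <- generate_truth_network(4, 12, mean_out_degree = 3, seed = 1)
#' atlas <- simulate_atlas(truth, n_tissues = 6, seed = 1)
#' names(atlas$matrices)
#' @export
simulate_atlas <- function(truth, n_tissues = 21,
                           categories = default_tissue_categories(),
                           te_sigma = 1, noise_sd = 0.25,
                           detection_dropout = 0.02,
                           specific_fraction = 0.05,
                           te_range = c(0.25, 4), fpkm_scale = 8,
                           seed = 1) {
  stopifnot(inherits(truth, "grn_truth"))
  n_tissues <- check_count(n_tissues, "n_tissues", min = 2L)
  if (length(categories) < 1L) abort("`categories` must be nonempty.")
  check_scalar_number(te_sigma, "te_sigma", lower = 0)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(detection_dropout, "detection_dropout", lower = 0)
  if (detection_dropout >= 1) abort("`detection_dropout` must be < 1.")
  check_scalar_number(specific_fraction, "specific_fraction",
                      lower = 0, upper = 1)

  tfs <- truth$regulators
  tgs <- truth$targets
  genes <- c(tfs, tgs)
  n_tf <- length(tfs)
  n_tg <- length(tgs)
  n_g <- length(genes)
  tissues <- sprintf("t%02d", seq_len(n_tissues))
  tissue_cat <- categories[(seq_len(n_tissues) - 1L) %% length(categories) + 1L]

  set.seed(seed_for(seed, "atlas"))

  # (1) TF mRNA: lognormal baseline x tissue x gene-by-tissue variation
  b_tf <- stats::rnorm(n_tf, log(8), 1.0)
  u_t <- stats::rnorm(n_tissues, 0, 0.3)
  e_tf <- matrix(stats::rnorm(n_tf * n_tissues, 0, 0.7), n_tf, n_tissues)
  m_tf <- exp(outer(b_tf, u_t, `+`) + e_tf)

  # (2) TE per gene x tissue, clipped to the observed real-data range
  te <- matrix(exp(stats::rnorm(n_g * n_tissues, 0, te_sigma)),
               n_g, n_tissues, dimnames = list(genes, tissues))
  te <- pmin(pmax(te, te_range[1]), te_range[2])

  # tissue-category specificity mask (TRUE = expressed)
  n_spec <- floor(specific_fraction * n_g)
  spec_idx <- if (n_spec > 0) sample.int(n_g, n_spec) else integer(0)
  spec_cat <- if (n_spec > 0) sample(unique(tissue_cat), n_spec, replace = TRUE)
              else character(0)
  mask <- matrix(TRUE, n_g, n_tissues, dimnames = list(genes, tissues))
  for (i in seq_along(spec_idx)) {
    mask[spec_idx[i], tissue_cat != spec_cat[i]] <- FALSE
  }

  r_tf <- m_tf * te[seq_len(n_tf), , drop = FALSE]
  m_tf <- m_tf * mask[seq_len(n_tf), , drop = FALSE]
  r_tf <- r_tf * mask[seq_len(n_tf), , drop = FALSE]

  # (3) regulator signal = standardized log1p TF translatome
  s <- scale(t(log1p(r_tf)))           # tissues x TFs
  s[, !is.finite(colSds_safe(s))] <- 0
  s[!is.finite(s)] <- 0

  beta <- matrix(0, n_tf, n_tg, dimnames = list(tfs, tgs))
  beta[cbind(match(truth$edges$regulator, tfs),
             match(truth$edges$target, tgs))] <- truth$edges$effect

  alpha <- stats::rnorm(n_tg, 1.5, 0.6)
  eps <- matrix(stats::rnorm(n_tg * n_tissues, 0, noise_sd), n_tissues, n_tg)
  drive <- s %*% beta                  # tissues x targets
  m_tg <- t(fpkm_scale * softplus(sweep(drive + eps, 2, alpha, `+`)))

  # (4) target translatome = target mRNA x own TE
  r_tg <- m_tg * te[n_tf + seq_len(n_tg), , drop = FALSE]
  m_tg <- m_tg * mask[n_tf + seq_len(n_tg), , drop = FALSE]
  r_tg <- r_tg * mask[n_tf + seq_len(n_tg), , drop = FALSE]

  rna_true <- rbind(m_tf, m_tg)
  ribo_true <- rbind(r_tf, r_tg)
  dimnames(rna_true) <- dimnames(ribo_true) <- list(genes, tissues)

  lognoise <- function(x) {
    if (noise_sd == 0) return(x)
    x * exp(matrix(stats::rnorm(length(x), 0, noise_sd), nrow(x), ncol(x)))
  }
  # (5) observed sources: two replicates; bulked = mean of three hidden reps
  make_source <- function(x, suffix) {
    out <- if (identical(suffix, "bulked")) {
      (lognoise(x) + lognoise(x) + lognoise(x)) / 3
    } else {
      lognoise(x)
    }
    colnames(out) <- paste0(tissues, "_", suffix)
    out
  }
  raw <- list(
    rna_rep1  = make_source(rna_true, "rep1"),
    rna_rep2  = make_source(rna_true, "rep2"),
    rna_bulked = make_source(rna_true, "bulked"),
    ribo_rep1 = make_source(ribo_true, "rep1"),
    ribo_rep2 = make_source(ribo_true, "rep2"),
    ribo_bulked = make_source(ribo_true, "bulked")
  )

  # (6) detection dropout
  if (detection_dropout > 0) {
    for (nm in names(raw)) {
      drop <- matrix(stats::runif(length(raw[[nm]])) < detection_dropout,
                     nrow(raw[[nm]]), ncol(raw[[nm]]))
      raw[[nm]][drop] <- 0
    }
  }

  omics_of <- function(nm) {
    if (startsWith(nm, "rna")) "transcriptome" else "translatome"
  }
  source_of <- function(nm) sub("^(rna|ribo)_", "", nm)
  matrices <- purrr::imap(raw, function(m, nm) {
    expr_from_values(m, omics = omics_of(nm), source = source_of(nm))
  })
  matrices <- matrices[c("rna_rep1", "rna_rep2", "ribo_rep1", "ribo_rep2",
                         "rna_bulked", "ribo_bulked")]

  metadata <- tidyr::expand_grid(
    tissue = tissues,
    source = c("rep1", "rep2", "bulked", "mean")
  )
  metadata <- tibble::tibble(
    sample_id = paste0(metadata$tissue, "_", metadata$source),
    tissue_category = tissue_cat[match(metadata$tissue, tissues)],
    source = metadata$source
  )

  te_profile <- dplyr::bind_cols(
    tibble::tibble(gene_id = genes),
    tibble::as_tibble(te, .name_repair = "minimal")
  )

  specific_genes <- tibble::tibble(gene_id = genes[spec_idx],
                                   tissue_category = spec_cat)

  structure(
    list(
      matrices = matrices, metadata = metadata, te_profile = te_profile,
      specific_genes = specific_genes, truth = truth,
      params = list(n_tissues = n_tissues, categories = categories,
                    te_sigma = te_sigma, noise_sd = noise_sd,
                    detection_dropout = detection_dropout,
                    specific_fraction = specific_fraction,
                    te_range = te_range, fpkm_scale = fpkm_scale,
                    seed = as.integer(seed))
    ),
    class = "grn_atlas"
  )
}

colSds_safe <- function(m) apply(m, 2, stats::sd)

#' @export
print.grn_atlas <- function(x, ...) {
  cat(sprintf(
    "<grn_atlas> %d genes x %d tissues; layers: %s (seed %d)\n",
    nrow(x$matrices[[1]]), x$params$n_tissues,
    paste(names(x$matrices), collapse = ", "), x$params$seed))
  invisible(x)
}

#' Extract one layer/source matrix from an atlas
#'
#' The `mean` source is computed on demand as the per-tissue average of the
#' two replicates (sample ids suffixed `_mean`), mirroring how the
#' replicated atlas is collapsed before network inference.
#'
#' @param atlas A `grn_atlas`.
#' @param omics `"rna"` or `"ribo"`.
#' @param source `"mean"`, `"bulked"`, `"rep1"` or `"rep2"`.
#' @return An expression-matrix tibble.
#' @export
atlas_layer <- function(atlas, omics = c("rna", "ribo"),
                        source = c("mean", "bulked", "rep1", "rep2")) {
  omics <- match.arg(omics)
  source <- match.arg(source)
  omics_label <- if (omics == "rna") "transcriptome" else "translatome"
  if (source != "mean") {
    return(atlas$matrices[[paste0(omics, "_", source)]])
  }
  r1 <- expr_values(atlas$matrices[[paste0(omics, "_rep1")]])
  r2 <- expr_values(atlas$matrices[[paste0(omics, "_rep2")]])
  m <- (r1 + r2) / 2
  colnames(m) <- sub("_rep1$", "_mean", colnames(m))
  expr_from_values(m, omics = omics_label, source = "mean")
}

#' Derive a ChIP-seq-like gold standard from a truth network
#'
#' Per TF, a random `observed_fraction` of its true targets is retained
#' (emulating incomplete binding evidence) and `spurious_fraction` times
#' that many non-targets are added (emulating binding without regulation).
#' Counts are rounded: with `d` true targets a TF contributes
#' `round(observed_fraction * d)` true and
#' `round(spurious_fraction * round(observed_fraction * d))` spurious pairs.
#'
#' @param truth A `grn_truth`.
#' @param observed_fraction Fraction of true targets observed, in (0, 1].
#' @param spurious_fraction Spurious pairs per observed pair, >= 0.
#' @param seed Integer seed.
#' @return A `gold_standard`: list with `edges` (tibble `tf`, `target`),
#'   `tf_universe` and `target_universe`.
#' @export
make_gold_standard <- function(truth, observed_fraction = 0.8,
                               spurious_fraction = 0.25, seed = 1) {
  stopifnot(inherits(truth, "grn_truth"))
  if (nrow(truth$edges) == 0) abort("truth network has no edges.")
  check_scalar_number(observed_fraction, "observed_fraction",
                      lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar_number(spurious_fraction, "spurious_fraction", lower = 0)

  set.seed(seed_for(seed, "gold"))
  by_tf <- split(truth$edges$target, truth$edges$regulator)
  edges <- purrr::imap_dfr(by_tf, function(tg, tf) {
    n_obs <- round(observed_fraction * length(tg))
    obs <- if (n_obs > 0) sample(tg, n_obs) else character(0)
    n_spur <- round(spurious_fraction * n_obs)
    pool <- setdiff(truth$targets, tg)
    spur <- if (n_spur > 0) sample(pool, min(n_spur, length(pool)))
            else character(0)
    tibble::tibble(tf = tf, target = c(obs, spur))
  })
  gold_standard(edges, tf_universe = truth$regulators,
                target_universe = truth$targets)
}

#' Construct a gold standard from an edge table
#'
#' @param edges Tibble or data frame with columns `tf` and `target`.
#' @param tf_universe,target_universe Declared id universes; default to the
#'   ids present in `edges`.
#' @return A `gold_standard` object.
#' @export
gold_standard <- function(edges, tf_universe = NULL, target_universe = NULL) {
  edges <- tibble::as_tibble(edges)[, c("tf", "target")]
  edges <- dplyr::distinct(edges)
  tf_universe <- tf_universe %||% sort(unique(edges$tf))
  target_universe <- target_universe %||% sort(unique(edges$target))
  if (!all(edges$tf %in% tf_universe)) {
    abort("all gold TFs must be in `tf_universe`.")
  }
  if (!all(edges$target %in% target_universe)) {
    abort("all gold targets must be in `target_universe`.")
  }
  structure(list(edges = edges, tf_universe = tf_universe,
                 target_universe = target_universe),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("<gold_standard> %d pairs, %d TFs, universe %d targets\n",
              nrow(x$edges), length(unique(x$edges$tf)),
              length(x$target_universe)))
  invisible(x)
}

#' Read/write gold-standard edge tables (two-column TSV: tf, target)
#'
#' @param path File path.
#' @param x A `gold_standard`.
#' @inheritParams gold_standard
#' @return `read_gold_standard()` returns a `gold_standard`;
#'   `write_gold_standard()` returns `path` invisibly.
#' @export
read_gold_standard <- function(path, tf_universe = NULL,
                               target_universe = NULL) {
  tbl <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  names(tbl)[1:2] <- c("tf", "target")
  gold_standard(tbl, tf_universe, target_universe)
}

#' @rdname read_gold_standard
#' @export
write_gold_standard <- function(x, path) {
  readr::write_tsv(x$edges, path, progress = FALSE)
  invisible(path)
}

#' Write all atlas artifacts to a directory
#'
#' Serializes the six matrices, sample metadata, TE profile and truth edge
#' table as TSV files.
#'
#' @param atlas A `grn_atlas`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (nm in names(atlas$matrices)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_expr_matrix(atlas$matrices[[nm]], p)
    paths[nm] <- p
  }
  paths["metadata"] <- file.path(dir, "sample_metadata.tsv")
  write_metadata(atlas$metadata, paths["metadata"])
  paths["te_profile"] <- file.path(dir, "te_profile.tsv")
  readr::write_tsv(atlas$te_profile, paths["te_profile"], progress = FALSE)
  paths["truth_edges"] <- file.path(dir, "truth_edges.tsv")
  readr::write_tsv(atlas$truth$edges, paths["truth_edges"], progress = FALSE)
  invisible(paths)
}
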