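#' Filter genes for network construction
#'
#' Keeps genes with FPKM at or above `fpkm_min` in at least one sample and
#' non-zero abundance in at least `min_nonzero` samples — the expression
#' filter applied before inferring regulatory networks.
#'
#' @param x An expression-matrix tibble (see [expr_matrix()]).
#' @param fpkm_min Minimum FPKM required in at least one sample.
#' @param min_nonzero Minimum number of samples with non-zero abundance.
#' @return Character vector of gene ids passing both rules.
#' @examples
#' m <- expr_matrix(tibble::tibble(
#'   gene_id = c("a", "b", "c"),
#'   t1 = c(1.2, 0.9, 5), t2 = c(0.5, 0.8, 0), t3 = c(0.3, 0.7, 0)
#' ))
#' filter_grn_genes(m)  # "a": b never reaches 1, c non-zero in 1 sample
#' @export
filter_grn_genes <- function(x, fpkm_min = 1, min_nonzero = 3) {
  check_scalar_number(fpkm_min, "fpkm_min", lower = 0)
  min_nonzero <- check_count(min_nonzero, "min_nonzero", min = 0L)
  vals <- expr_values(x)
  if (ncol(vals) < min_nonzero) {
    warn(sprintf(
      "matrix has %d sample(s) but min_nonzero = %d; no gene can pass.",
      ncol(vals), min_nonzero))
  }
  keep <- apply(vals, 1, max) >= fpkm_min &
    rowSums(vals > 0) >= min_nonzero
  rownames(vals)[keep]
}

#' Select regulators detectable at both omics layers
#'
#' A TF qualifies as a regulator only if it passes [filter_grn_genes()] in
#' both the transcriptome and the translatome matrix of the same source.
#'
#' @param tf_ids Candidate TF gene ids.
#' @param rna,ribo Paired (harmonized) expression matrices.
#' @inheritParams filter_grn_genes
#' @return Character vector of regulator ids.
#' @export
select_regulators <- function(tf_ids, rna, ribo, fpkm_min = 1,
                              min_nonzero = 3) {
  if (length(tf_ids) == 0) abort("`tf_ids` must be nonempty.")
  present <- intersect(tf_ids, intersect(expr_genes(rna), expr_genes(ribo)))
  if (length(present) == 0) {
    warn("none of `tf_ids` are present in the matrices.")
    return(character(0))
  }
  pass_rna <- filter_grn_genes(rna, fpkm_min, min_nonzero)
  pass_ribo <- filter_grn_genes(ribo, fpkm_min, min_nonzero)
  intersect(intersect(present, pass_rna), pass_ribo)
}

#' Translational efficiency per gene and sample
#'
#' TE is the ratio of translatome to transcriptome abundance. Entries where
#' the transcriptome denominator is below `detect_min` are masked (TE = NA
#' with a reason) rather than propagated as infinities. No pseudocount is
#' used.
#'
#' @param ribo,rna Paired expression matrices with identical sample sets.
#' @param detect_min Minimum RNA FPKM for TE to be defined.
#' @return A long tibble: `gene_id`, `sample_id`, `rna`, `ribo`, `te`,
#'   `masked`, `reason`.
#' @export
compute_te <- function(ribo, rna, detect_min = 1) {
  if (!identical(expr_samples(ribo), expr_samples(rna))) {
    abort("ribo and rna must share an identical ordered sample set.")
  }
  h <- harmonize_pair(ribo, rna)
  vb <- expr_values(h$a)
  vr <- expr_values(h$b)
  ok <- vr >= detect_min
  te <- ifelse(ok, vb / vr, NA_real_)
  tibble::tibble(
    gene_id = rep(rownames(vr), times = ncol(vr)),
    sample_id = rep(colnames(vr), each = nrow(vr)),
    rna = as.vector(vr),
    ribo = as.vector(vb),
    te = as.vector(te),
    masked = !as.vector(ok),
    reason = ifelse(as.vector(ok), NA_character_, "rna below detect_min")
  )
}

#' Tissue-specific expression (SEG) report
#'
#' A gene is specifically expressed in a tissue category, at a given omics
#' layer, when it is detected (abundance above the detection threshold) in
#' at least one sample of that category and in no sample of any other
#' category. SEGs are the union of specifically transcribed and
#' specifically translated genes; the per-category mean SEG count divides
#' by the number of samples in the category, so categories with more
#' samples are not inflated.
#'
#' @param rna,ribo Paired expression matrices.
#' @param metadata Tibble with `sample_id` and `tissue_category` covering
#'   all samples of the matrices.
#' @param detect_min Detection threshold: a value is "detected" when it is
#'   strictly positive and at least `detect_min` (default 0, i.e. FPKM > 0).
#' @return A `seg_report`: list with `genes` (gene_id, category,
#'   specificity in transcribed/translated/both) and `summary` (per
#'   category: sample count, layer-specific counts, `seg_count`,
#'   `mean_seg`).
#' @export
detect_segs <- function(rna, ribo, metadata, detect_min = 0) {
  samples <- expr_samples(rna)
  if (!identical(samples, expr_samples(ribo))) {
    abort("rna and ribo must share an identical ordered sample set.")
  }
  cat_of <- metadata$tissue_category[match(samples, metadata$sample_id)]
  if (anyNA(cat_of)) abort("metadata must cover every sample.")
  cats <- unique(cat_of)
  if (length(cats) == 1L) {
    warn("single tissue category: every detected gene is trivially specific.")
  }

  specific_in <- function(vals) {
    det <- vals > 0 & vals >= detect_min
    # per-category detection indicator per gene
    by_cat <- vapply(cats, function(cc) {
      rowSums(det[, cat_of == cc, drop = FALSE]) > 0
    }, logical(nrow(det)))
    by_cat <- matrix(by_cat, nrow = nrow(det))
    n_cats_detected <- rowSums(by_cat)
    out <- rep(NA_character_, nrow(det))
    one <- which(n_cats_detected == 1L)
    if (length(one)) {
      out[one] <- cats[apply(by_cat[one, , drop = FALSE], 1, which)]
    }
    out
  }
  spec_rna <- specific_in(expr_values(rna))
  spec_ribo <- specific_in(expr_values(ribo))

  genes <- tibble::tibble(
    gene_id = expr_genes(rna),
    transcribed_in = spec_rna,
    translated_in = spec_ribo
  )
  long <- dplyr::bind_rows(
    tibble::tibble(gene_id = genes$gene_id, category = genes$transcribed_in,
                   layer = "transcribed"),
    tibble::tibble(gene_id = genes$gene_id, category = genes$translated_in,
                   layer = "translated")
  )
  long <- long[!is.na(long$category), ]
  gene_tbl <- long |>
    dplyr::group_by(.data$gene_id, .data$category) |>
    dplyr::summarise(
      specificity = if (dplyr::n() == 2L) "both" else .data$layer[1],
      .groups = "drop"
    )

  n_samples <- vapply(cats, function(cc) sum(cat_of == cc), integer(1))
  summary <- gene_tbl |>
    dplyr::count(.data$category, .data$specificity) |>
    tidyr::pivot_wider(names_from = "specificity", values_from = "n",
                       values_fill = 0L)
  for (col in c("transcribed", "translated", "both")) {
    if (!col %in% names(summary)) summary[[col]] <- 0L
  }
  summary <- tibble::tibble(category = cats) |>
    dplyr::left_join(summary, by = "category") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                ~ tidyr::replace_na(.x, 0L)))
  summary$n_samples <- unname(n_samples[match(summary$category, cats)])
  summary$seg_count <- summary$transcribed + summary$translated + summary$both
  summary$mean_seg <- summary$seg_count / summary$n_samples

  structure(list(genes = gene_tbl, summary = summary,
                 detect_min = detect_min, categories = cats),
            class = "seg_report")
}

#' @export
print.seg_report <- function(x, ...) {
  cat(sprintf("<seg_report> %d categories, %d specific genes\n",
              length(x$categories), nrow(x$genes)))
  print(x$summary)
  invisible(x)
}

#' Pearson correlation report between two matrices
#'
#' Computes Pearson's r per matched sample (`axis = "per_sample_pair"`,
#' across shared genes — e.g. replicate agreement) or per matched gene
#' (`axis = "per_gene"`, across shared samples — e.g. cross-omics profile
#' agreement). Pairs with fewer than 3 observations or zero variance on
#' either side are masked with a reason rather than returning NaN.
#'
#' @param a,b Expression matrices.
#' @param axis `"per_sample_pair"` or `"per_gene"`.
#' @return Tibble: `id`, `r`, `n_obs`, `masked`, `reason`.
#' @export
correlation_report <- function(a, b, axis = c("per_gene", "per_sample_pair")) {
  axis <- match.arg(axis)
  va <- expr_values(a)
  vb <- expr_values(b)
  if (axis == "per_gene") {
    shared_s <- intersect(colnames(va), colnames(vb))
    shared_g <- intersect(rownames(va), rownames(vb))
    ids <- shared_g
    get <- function(id) list(x = va[id, shared_s], y = vb[id, shared_s])
  } else {
    shared_g <- intersect(rownames(va), rownames(vb))
    shared_s <- intersect(colnames(va), colnames(vb))
    ids <- shared_s
    get <- function(id) list(x = va[shared_g, id], y = vb[shared_g, id])
  }
  if (length(ids) == 0) abort("no shared ids between the matrices.")
  rows <- purrr::map_dfr(ids, function(id) {
    p <- get(id)
    n <- length(p$x)
    if (n < 3) {
      return(tibble::tibble(id = id, r = NA_real_, n_obs = n, masked = TRUE,
                            reason = "fewer than 3 observations"))
    }
    if (stats::sd(p$x) == 0 || stats::sd(p$y) == 0) {
      return(tibble::tibble(id = id, r = NA_real_, n_obs = n, masked = TRUE,
                            reason = "zero variance"))
    }
    tibble::tibble(id = id, r = stats::cor(p$x, p$y), n_obs = n,
                   masked = FALSE, reason = NA_character_)
  })
  rows
}
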