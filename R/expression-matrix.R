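#' Expression matrices as tidy tibbles
#'
#' An expression matrix is a wide tibble whose first column is `gene_id` and
#' whose remaining columns are numeric per-sample FPKM abundances. This is
#' the same shape as the on-disk TSV dialect (header of sample ids, first
#' column gene id), so matrices round-trip through [read_expr_matrix()] /
#' [write_expr_matrix()] unchanged. The omics layer (`"transcriptome"` or
#' `"translatome"`) and the data source (`"mean"`, `"bulked"`, `"rep1"`,
#' `"rep2"`) travel as attributes set by `expr_matrix()`.
#'
#' @param x A data frame with a `gene_id` character column followed by
#'   numeric sample columns.
#' @param omics Omics layer label, `"transcriptome"` or `"translatome"`.
#' @param source Data source label: `"mean"`, `"bulked"`, `"rep1"` or `"rep2"`.
#' @return A tibble with `gene_id` first, attributes `omics` and `source`.
#' @examples
#' m <- expr_matrix(
#'   tibble::tibble(gene_id = c("g1", "g2"), s1 = c(1, 0), s2 = c(2, 3)),
#'   omics = "transcriptome", source = "mean"
#' )
#' expr_genes(m)
#' @export
expr_matrix <- function(x, omics = c("transcriptome", "translatome"),
                        source = c("mean", "bulked", "rep1", "rep2")) {
  omics <- match.arg(omics)
  source <- match.arg(source)
  x <- tibble::as_tibble(x)
  if (!identical(names(x)[1], "gene_id")) {
    abort("first column of an expression matrix must be `gene_id`.")
  }
  if (anyDuplicated(x$gene_id)) abort("`gene_id` values must be unique.")
  vals <- as.matrix(x[-1])
  if (!is.numeric(vals)) abort("sample columns must be numeric.")
  if (anyDuplicated(colnames(vals))) abort("sample ids must be unique.")
  if (any(!is.finite(vals))) abort("abundances must be finite.")
  if (any(vals < 0)) abort("FPKM abundances must be nonnegative.")
  attr(x, "omics") <- omics
  attr(x, "source") <- source
  x
}

#' @rdname expr_matrix
#' @export
expr_genes <- function(x) x$gene_id

#' @rdname expr_matrix
#' @export
expr_samples <- function(x) names(x)[-1]

#' Extract the numeric gene-by-sample matrix
#'
#' @param x An expression matrix tibble (see [expr_matrix()]).
#' @return A numeric matrix with gene ids as row names.
#' @export
expr_values <- function(x) {
  m <- as.matrix(x[-1])
  rownames(m) <- x$gene_id
  m
}

# Rebuild a wide tibble from a numeric matrix with gene rownames.
expr_from_values <- function(m, omics, source) {
  tbl <- tibble::as_tibble(m, .name_repair = "minimal")
  tbl <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)), tbl)
  expr_matrix(tbl, omics = omics, source = source)
}

#' Harmonize a pair of expression matrices
#'
#' Restricts two matrices (typically the RNA-seq and Ribo-seq layers of the
#' same source) to their shared gene universe, preserving the first matrix's
#' gene order. Gene ids present in only one matrix are dropped and reported.
#' Sample sets are checked for equality when `require_samples = TRUE`.
#'
#' @param a,b Expression matrices.
#' @param require_samples Require identical ordered sample columns.
#' @return A list with elements `a`, `b` (harmonized matrices) and
#'   `dropped` (character vector of gene ids removed from either side).
#' @export
harmonize_pair <- function(a, b, require_samples = TRUE) {
  if (require_samples && !identical(expr_samples(a), expr_samples(b))) {
    abort("matrices must share an identical ordered sample set.")
  }
  shared <- intersect(expr_genes(a), expr_genes(b))
  dropped <- setdiff(union(expr_genes(a), expr_genes(b)), shared)
  if (length(dropped)) {
    inform(sprintf("harmonize_pair: dropped %d gene(s) absent from one layer.",
                   length(dropped)))
  }
  keep <- function(x) x[match(shared, x$gene_id), , drop = FALSE]
  a2 <- keep(a)
  b2 <- keep(b)
  attributes(a2)[c("omics", "source")] <- attributes(a)[c("omics", "source")]
  attributes(b2)[c("omics", "source")] <- attributes(b)[c("omics", "source")]
  list(a = a2, b = b2, dropped = dropped)
}

#' Read and write expression matrices and sample metadata
#'
#' Gene-by-sample TSV with a header row of sample ids and `gene_id` as the
#' first column; metadata TSV with columns `sample_id`, `tissue_category`,
#' `source`.
#'
#' @param path File path.
#' @param x Object to write.
#' @inheritParams expr_matrix
#' @return `read_expr_matrix()` returns an expression matrix tibble;
#'   `read_metadata()` a tibble; the writers return `path` invisibly.
#' @export
read_expr_matrix <- function(path, omics = c("transcriptome", "translatome"),
                             source = c("mean", "bulked", "rep1", "rep2")) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1] <- "gene_id"
  expr_matrix(tbl, omics = match.arg(omics), source = match.arg(source))
}

#' @rdname read_expr_matrix
#' @export
write_expr_matrix <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_expr_matrix
#' @export
read_metadata <- function(path) {
  readr::read_tsv(path, col_types = "ccc", progress = FALSE)
}

#' @rdname read_expr_matrix
#' @export
write_metadata <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
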