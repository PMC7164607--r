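#' Expression matrix with library metadata
#'
#' Container for a gene-by-library expression table together with per-library
#' metadata. Values may be raw unique-read counts (`layer = "raw_counts"`),
#' reads per million mapped reads (`layer = "rpm"`), or any other
#' single-layer normalization (`layer = "normalized"`). Downstream screens
#' apply to whichever layer is loaded; the package does not convert between
#' external normalizations.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   libraries in columns (colnames = library ids). No missing cells,
#'   all values >= 0; the raw-counts layer must be integral.
#' @param libraries Data frame of library metadata with at least a
#'   `library_id` column matching `colnames(values)`. The conventional
#'   columns are `library_id`, `cultivar`, `tree`, `tissue`
#'   (flower/ovary/whole_fruit/endocarp), `timepoint`, `genotype_group`
#'   (normal/stoneless) and `total_mapped_reads`.
#' @param layer One of `"raw_counts"`, `"rpm"`, `"normalized"`.
#'
#' @return An object of class `expr_matrix`: a list with elements
#'   `values`, `libraries` (tibble, ordered as the matrix columns) and
#'   `layer`.
#' @seealso [read_expression_matrix()], [to_rpm()], [summarize_genes()]
#' @export
expression_matrix <- function(values,
                              libraries,
                              layer = c("raw_counts", "rpm", "normalized")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_fmt("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort_fmt("'values' must carry gene ids as rownames and library ids as colnames")
  }
  if (anyDuplicated(rownames(values))) abort_fmt("duplicate gene ids")
  if (anyDuplicated(colnames(values))) abort_fmt("duplicate library ids")
  if (anyNA(values)) abort_fmt("expression matrix contains missing cells")
  if (any(values < 0)) abort_fmt("expression values must be nonnegative")
  if (layer == "raw_counts" && any(values != floor(values))) {
    abort_fmt("raw_counts layer must contain integer counts")
  }

  libraries <- tibble::as_tibble(libraries)
  if (!"library_id" %in% names(libraries)) {
    abort_fmt("library metadata must have a 'library_id' column")
  }
  missing <- setdiff(colnames(values), libraries$library_id)
  if (length(missing) > 0) {
    abort_fmt(
      "library '%s' present in the matrix but absent from metadata",
      missing[1]
    )
  }
  # order metadata as the matrix columns, dropping unused metadata rows
  libraries <- libraries[match(colnames(values), libraries$library_id), ]

  structure(
    list(values = values, libraries = libraries, layer = layer),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d libraries, layer '%s'\n",
    nrow(x$values), ncol(x$values), x$layer
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
library_ids <- function(x) colnames(x$values)

#' Read an expression matrix and its library metadata
#'
#' Reads a delimited gene-by-library table (first column gene ids, one
#' column per library) plus a metadata table mapping library ids to their
#' design variables. The delimiter is inferred from the file extension
#' (`.csv` comma, otherwise tab).
#'
#' @param path Path to the matrix file.
#' @param meta_path Path to the metadata file (must contain `library_id`;
#'   typically also `cultivar`, `tree`, `tissue`, `timepoint`,
#'   `genotype_group`, `total_mapped_reads`).
#' @param layer Layer tag for the values; see [expression_matrix()].
#' @return An [expression_matrix()] with libraries ordered as in the
#'   metadata file.
#' @export
read_expression_matrix <- function(path, meta_path,
                                   layer = c("raw_counts", "rpm", "normalized")) {
  layer <- match.arg(layer)
  mat_df <- read_delim_auto(path)
  if (ncol(mat_df) < 2) abort_fmt("matrix file needs a gene id column plus >= 1 library")
  genes <- as.character(mat_df[[1]])
  value_cols <- mat_df[-1]
  bad <- !vapply(value_cols, is.numeric, logical(1))
  if (any(bad)) {
    col <- names(value_cols)[which(bad)[1]]
    row <- which(is.na(suppressWarnings(as.numeric(value_cols[[col]]))))[1]
    abort_fmt(
      "non-numeric cell in library '%s' (gene '%s')",
      col, genes[if (is.na(row)) 1 else row]
    )
  }
  values <- as.matrix(value_cols)
  rownames(values) <- genes

  meta <- read_delim_auto(meta_path)
  meta$library_id <- as.character(meta$library_id)
  missing <- setdiff(colnames(values), meta$library_id)
  if (length(missing) > 0) {
    abort_fmt("library '%s' missing from metadata '%s'", missing[1], meta_path)
  }
  # libraries in metadata order
  keep <- meta$library_id[meta$library_id %in% colnames(values)]
  expression_matrix(values[, keep, drop = FALSE], meta, layer = layer)
}

#' Write an expression matrix (and optionally its metadata) to disk
#'
#' @param x An [expression_matrix()].
#' @param path Output path for the matrix (`.csv` comma, otherwise tab).
#' @param meta_path Optional output path for the library metadata.
#' @return `x`, invisibly.
#' @export
write_expression_matrix <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- tibble::as_tibble(x$values, rownames = "gene_id")
  write_delim_auto(df, path)
  if (!is.null(meta_path)) write_delim_auto(x$libraries, meta_path)
  invisible(x)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort_fmt("file not found: %s", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

write_delim_auto <- function(df, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(df, path, progress = FALSE)
  } else {
    readr::write_tsv(df, path, progress = FALSE)
  }
}

#' Convert raw counts to reads per million (RPM)
#'
#' Divides each library's counts by that library's total mapped reads and
#' scales to one million. Totals come either from the metadata column
#' `total_mapped_reads` (the usual case, where the matrix holds only a
#' subset of the transcriptome) or from the matrix column sums.
#'
#' @param x An [expression_matrix()] with `layer = "raw_counts"`.
#' @param totals_source `"metadata"` or `"column_sum"`.
#' @return An [expression_matrix()] with `layer = "rpm"`.
#' @export
to_rpm <- function(x, totals_source = c("metadata", "column_sum")) {
  stopifnot(inherits(x, "expr_matrix"))
  totals_source <- match.arg(totals_source)
  if (x$layer != "raw_counts") {
    abort_fmt("RPM conversion requires the raw_counts layer (got '%s')", x$layer)
  }
  totals <- switch(totals_source,
    metadata = {
      if (!"total_mapped_reads" %in% names(x$libraries)) {
        abort_fmt("metadata has no 'total_mapped_reads' column")
      }
      as.numeric(x$libraries$total_mapped_reads)
    },
    column_sum = colSums(x$values)
  )
  if (anyNA(totals) || any(totals <= 0)) {
    bad <- library_ids(x)[which(is.na(totals) | totals <= 0)[1]]
    abort_fmt("library '%s' has a zero or missing read total", bad)
  }
  rpm <- sweep(x$values, 2, totals, "/") * 1e6
  out <- x
  out$values <- rpm
  out$layer <- "rpm"
  out
}
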