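#' Per-gene expression summary across libraries
#'
#' Computes the descriptive row reported for each candidate reference
#' gene: mean, standard deviation, highest and lowest library value, the
#' high/low ratio, and the coefficient of variation in percent
#' (100 * StDev / mean). The high/low ratio is the span statistic used to
#' require "< 2-fold" variation of a usable reference gene; the CV is the
#' overall dispersion screen.
#'
#' @param x An [expression_matrix()].
#' @param gene Gene id (must be present in `x`).
#' @param library_subset Optional character vector of library ids to
#'   restrict the summary to (default: all libraries).
#' @param sd_denominator `"n-1"` (sample standard deviation, default) or
#'   `"n"` (population form). Printed CVs in typical reports are rounded
#'   to integer percent and consistent with either convention.
#' @return A one-row tibble with columns `gene_id`, `mean`, `stdev`,
#'   `high`, `low`, `high_low_ratio`, `cv_percent` and logical flags
#'   `ratio_undefined` (lowest value is 0) and `stdev_undefined`
#'   (single-library subset). Undefined quantities are `NA`.
#' @examples
#' m <- expression_matrix(
#'   matrix(c(5, 1, 3, 7), 2, 2,
#'     dimnames = list(c("g1", "g2"), c("L1", "L2"))
#'   ),
#'   data.frame(library_id = c("L1", "L2")),
#'   layer = "rpm"
#' )
#' summarize_gene(m, "g1")
#' @export
summarize_gene <- function(x, gene, library_subset = NULL,
                           sd_denominator = c("n-1", "n")) {
  stopifnot(inherits(x, "expr_matrix"))
  sd_denominator <- match.arg(sd_denominator)
  if (!gene %in% gene_ids(x)) abort_fmt("gene '%s' not in matrix", gene)
  v <- x$values[gene, ]
  if (!is.null(library_subset)) {
    if (length(library_subset) == 0) abort_fmt("empty library subset")
    missing <- setdiff(library_subset, library_ids(x))
    if (length(missing) > 0) abort_fmt("library '%s' not in matrix", missing[1])
    v <- v[library_subset]
  }
  n <- length(v)
  m <- mean(v)
  s <- if (n < 2) {
    NA_real_
  } else if (sd_denominator == "n-1") {
    stats::sd(v)
  } else {
    sqrt(mean((v - m)^2))
  }
  hi <- max(v)
  lo <- min(v)
  tibble::tibble(
    gene_id = gene,
    mean = m,
    stdev = s,
    high = hi,
    low = lo,
    high_low_ratio = if (lo > 0) hi / lo else NA_real_,
    cv_percent = if (!is.na(s) && m > 0) 100 * s / m else NA_real_,
    ratio_undefined = lo == 0,
    stdev_undefined = n < 2
  )
}

#' Summary table for every gene in a matrix
#'
#' One [summarize_gene()] row per gene, in matrix order.
#'
#' @inheritParams summarize_gene
#' @return Tibble with one row per gene.
#' @export
summarize_genes <- function(x, library_subset = NULL,
                            sd_denominator = c("n-1", "n")) {
  stopifnot(inherits(x, "expr_matrix"))
  sd_denominator <- match.arg(sd_denominator)
  if (ncol(x$values) < 2 && is.null(library_subset)) {
    abort_fmt("gene summaries need >= 2 libraries")
  }
  purrr::map_dfr(
    gene_ids(x),
    function(g) summarize_gene(x, g, library_subset, sd_denominator)
  )
}

#' Format a gene summary table for reporting
#'
#' Applies the conventional report rounding: ratios to 2 decimal places,
#' CV to integer percent, means/StDev to 4 significant digits. Full
#' precision is retained by [summarize_genes()]; this is presentation
#' only.
#'
#' @param summary Tibble from [summarize_genes()].
#' @return Tibble with rounded columns; undefined ratios become `"-"`.
#' @export
format_gene_summary <- function(summary) {
  tibble::tibble(
    gene_id = summary$gene_id,
    mean = signif(summary$mean, 4),
    stdev = signif(summary$stdev, 4),
    high = signif(summary$high, 4),
    low = signif(summary$low, 4),
    high_low_ratio = ifelse(
      is.na(summary$high_low_ratio), "-",
      sprintf("%.2f", summary$high_low_ratio)
    ),
    cv_percent = ifelse(
      is.na(summary$cv_percent), "-",
      sprintf("%d%%", as.integer(round(summary$cv_percent)))
    )
  )
}

#' Write a gene summary table as delimited text
#'
#' @param summary Tibble from [summarize_genes()].
#' @param path Output path (`.csv` comma, otherwise tab).
#' @param rounded Apply [format_gene_summary()] before writing.
#' @return `summary`, invisibly.
#' @export
write_gene_summary <- function(summary, path, rounded = FALSE) {
  out <- if (rounded) format_gene_summary(summary) else
    summary[c("gene_id", "mean", "stdev", "high", "low",
              "high_low_ratio", "cv_percent")]
  write_delim_auto(out, path)
  invisible(summary)
}
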