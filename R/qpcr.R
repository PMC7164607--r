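#' Collapse technical qPCR replicates with the 0.5-cycle outlier rule
#'
#' Averages up to three technical replicate Cq values. With triplicates,
#' a replicate lying more than `outlier_delta` cycles from *both* other
#' replicates is discarded and the remaining two averaged; if all three
#' are mutually more than `outlier_delta` apart the reaction is marked
#' failed and no mean is returned. With exactly two replicates the rule
#' cannot identify an outlier, so both are averaged and flagged
#' `"unguarded"`; a single replicate is returned as-is.
#'
#' @param cqs Numeric vector of 1-3 positive, finite Cq values.
#' @param outlier_delta Discard distance in cycles (default 0.5).
#' @return A one-row tibble: `mean_cq` (NA when failed), `n_used`,
#'   `flag` (`"ok"`, `"outlier_discarded"`, `"unguarded"`, `"single"`,
#'   `"failed"`).
#' @examples
#' collapse_replicates(c(20.0, 20.1, 21.0)) # discards 21.0, mean 20.05
#' @export
collapse_replicates <- function(cqs, outlier_delta = 0.5) {
  cqs <- as.numeric(cqs)
  if (length(cqs) < 1 || length(cqs) > 3) {
    abort_fmt("expected 1-3 technical replicates, got %d", length(cqs))
  }
  if (anyNA(cqs) || any(!is.finite(cqs)) || any(cqs <= 0)) {
    abort_fmt("Cq values must be positive and finite")
  }
  out <- function(mean_cq, n_used, flag) {
    tibble::tibble(mean_cq = mean_cq, n_used = n_used, flag = flag)
  }
  if (length(cqs) == 1) return(out(cqs, 1L, "single"))
  if (length(cqs) == 2) return(out(mean(cqs), 2L, "unguarded"))

  d <- abs(outer(cqs, cqs, "-"))
  # replicate i is an outlier iff it is > delta from BOTH other replicates
  far <- vapply(1:3, function(i) all(d[i, -i] > outlier_delta), logical(1))
  if (all(d[upper.tri(d)] > outlier_delta)) {
    return(out(NA_real_, 0L, "failed"))
  }
  if (sum(far) == 1) {
    keep <- cqs[!far]
    return(out(mean(keep), 2L, "outlier_discarded"))
  }
  out(mean(cqs), 3L, "ok")
}

#' Collapse a long-format Cq table
#'
#' Applies [collapse_replicates()] per sample x gene.
#'
#' @param cq_long Data frame with columns `sample_id`, `gene_id`, `cq`
#'   (one row per technical replicate).
#' @param outlier_delta Discard distance in cycles.
#' @return Tibble with one row per sample x gene: `sample_id`,
#'   `gene_id`, `mean_cq`, `n_used`, `flag`.
#' @export
collapse_cq_table <- function(cq_long, outlier_delta = 0.5) {
  needed <- c("sample_id", "gene_id", "cq")
  if (!all(needed %in% names(cq_long))) {
    abort_fmt("Cq table needs columns %s", paste(needed, collapse = ", "))
  }
  cq_long |>
    dplyr::group_by(.data$sample_id, .data$gene_id) |>
    dplyr::summarise(
      collapse_replicates(.data$cq, outlier_delta),
      .groups = "drop"
    )
}

#' Amplification efficiency from a standard-curve slope
#'
#' `E = 100 * (10^(-1/slope) - 1)` percent: the per-cycle amplification
#' factor minus one. A slope of -3.32193 cycles per log10 dilution means
#' perfect doubling (100%).
#'
#' @param slope Standard-curve slope in cycles per log10(input); must be
#'   negative.
#' @return Efficiency in percent.
#' @export
efficiency_from_slope <- function(slope) {
  if (!is.finite(slope) || slope >= 0) {
    abort_fmt("a valid standard curve has a negative slope (got %s)", slope)
  }
  100 * (10^(-1 / slope) - 1)
}

#' Fit a standard curve to a serial-dilution series
#'
#' Ordinary least squares of mean Cq on log10(relative input amount),
#' the classical qPCR standard curve. The undiluted sample sits at
#' relative input 1, a fivefold series at 1, 1/5, 1/25, ...
#'
#' @param relative_input Positive relative input amounts (>= 3 distinct
#'   values).
#' @param cq Mean Cq at each input.
#' @param gene_id Optional label carried into the result.
#' @return A list of class `standard_curve`: `gene_id`, `slope`,
#'   `intercept`, `r_squared`, `efficiency_percent`, `n_points`.
#' @export
fit_standard_curve <- function(relative_input, cq, gene_id = NA_character_) {
  if (length(relative_input) != length(cq)) {
    abort_fmt("inputs and Cq values differ in length")
  }
  if (length(cq) < 3) abort_fmt("standard curve needs >= 3 dilution points")
  if (any(relative_input <= 0)) abort_fmt("relative inputs must be > 0")
  lx <- log10(relative_input)
  if (stats::var(lx) == 0) abort_fmt("dilution inputs have zero variance")
  fit <- stats::lm(cq ~ lx)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  # direct r^2 (summary.lm warns on exact fits, which noiseless series are)
  ss_tot <- sum((cq - mean(cq))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::resid(fit)^2) / ss_tot
  structure(
    list(
      gene_id = gene_id,
      slope = slope,
      intercept = intercept,
      r_squared = r2,
      efficiency_percent = if (slope < 0) efficiency_from_slope(slope) else NA_real_,
      n_points = length(cq)
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> %s: Cq = %.4f %+.4f * log10(input), r2 = %.4f, eff = %.1f%%\n",
    ifelse(is.na(x$gene_id), "(unnamed)", x$gene_id),
    x$intercept, x$slope, x$r_squared, x$efficiency_percent
  ))
  invisible(x)
}

#' Fit standard curves for every gene in a dilution table
#'
#' Technical replicates at each dilution point are collapsed with
#' [collapse_replicates()] before fitting.
#'
#' @param dilutions Data frame with columns `gene_id`, `relative_input`,
#'   `cq` (one row per replicate).
#' @param outlier_delta Replicate discard distance in cycles.
#' @return Tibble with one row per gene: `gene_id`, `slope`,
#'   `intercept`, `r_squared`, `efficiency_percent`, `n_points`.
#' @export
fit_standard_curves <- function(dilutions, outlier_delta = 0.5) {
  needed <- c("gene_id", "relative_input", "cq")
  if (!all(needed %in% names(dilutions))) {
    abort_fmt("dilution table needs columns %s", paste(needed, collapse = ", "))
  }
  means <- dilutions |>
    dplyr::group_by(.data$gene_id, .data$relative_input) |>
    dplyr::summarise(
      mean_cq = collapse_replicates(.data$cq, outlier_delta)$mean_cq,
      .groups = "drop"
    )
  means |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(df, key) {
      cv <- fit_standard_curve(df$relative_input, df$mean_cq, key$gene_id)
      tibble::tibble(
        slope = cv$slope, intercept = cv$intercept,
        r_squared = cv$r_squared,
        efficiency_percent = cv$efficiency_percent,
        n_points = cv$n_points
      )
    }) |>
    dplyr::ungroup()
}

#' Convert a Cq value to a relative quantity via a standard curve
#'
#' Inverts the curve: `quantity = 10^((cq - intercept) / slope)`,
#' expressed relative to the curve's undiluted input. Lower Cq means
#' more template.
#'
#' @param cq Cq value(s) in cycles.
#' @param curve A `standard_curve` from [fit_standard_curve()], or any
#'   list with `slope` and `intercept`.
#' @return Relative quantity (same length as `cq`).
#' @export
cq_to_quantity <- function(cq, curve) {
  if (!is.finite(curve$slope) || curve$slope >= 0) {
    abort_fmt("invalid standard curve (slope must be negative)")
  }
  10^((cq - curve$intercept) / curve$slope)
}

#' Full Cq-to-relative-quantity processing of a qPCR experiment
#'
#' Collapses technical replicates, fits per-gene standard curves from
#' the dilution series, and converts each mean Cq to a relative quantity
#' on that gene's curve. Failed reactions (replicates mutually
#' discordant) propagate as `NA` quantities.
#'
#' @param cq_long Long Cq table (`sample_id`, `gene_id`, `cq`).
#' @param dilutions Dilution table (`gene_id`, `relative_input`, `cq`).
#' @param outlier_delta Replicate discard distance in cycles.
#' @return A list of class `rq_result`: `quantities` (tibble sample_id,
#'   gene_id, mean_cq, quantity, flag), `curves` (tibble from
#'   [fit_standard_curves()]), `collapsed` (per-reaction means).
#' @export
process_qpcr <- function(cq_long, dilutions, outlier_delta = 0.5) {
  collapsed <- collapse_cq_table(cq_long, outlier_delta)
  curves <- fit_standard_curves(dilutions, outlier_delta)
  missing <- setdiff(unique(collapsed$gene_id), curves$gene_id)
  if (length(missing) > 0) {
    abort_fmt("no standard curve for gene '%s'", missing[1])
  }
  quantities <- collapsed |>
    dplyr::left_join(curves, by = "gene_id") |>
    dplyr::mutate(
      quantity = ifelse(
        is.na(.data$mean_cq), NA_real_,
        10^((.data$mean_cq - .data$intercept) / .data$slope)
      )
    ) |>
    dplyr::select(
      "sample_id", "gene_id", "mean_cq", "quantity", "flag"
    )
  structure(
    list(quantities = quantities, curves = curves, collapsed = collapsed),
    class = "rq_result"
  )
}

#' Reshape collapsed Cq values into a genes-by-samples matrix
#'
#' Builds the mean-Cq matrix that the stability algorithms consume
#' (stability ranking deliberately uses raw mean Cq values, not
#' efficiency-corrected quantities).
#'
#' @param collapsed Tibble from [collapse_cq_table()] (or the
#'   `collapsed` element of [process_qpcr()]).
#' @param genes Optional gene subset/order (default: all, sorted order
#'   of appearance).
#' @return Numeric matrix, genes in rows, samples in columns. Failed
#'   reactions become `NA` cells; the stability functions require a
#'   complete matrix, so callers must drop or impute such genes.
#' @export
cq_matrix_from_collapsed <- function(collapsed, genes = NULL) {
  wide <- collapsed |>
    dplyr::select("sample_id", "gene_id", "mean_cq") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "mean_cq")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$gene_id
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing) > 0) abort_fmt("gene '%s' not in Cq data", missing[1])
    m <- m[genes, , drop = FALSE]
  }
  m
}
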