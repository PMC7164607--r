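#' Define a normalization scheme
#'
#' A named set of reference genes whose per-sample geometric mean is the
#' normalization factor; an empty set means "non-normalized".
#'
#' @param name Scheme label.
#' @param reference_genes Character vector of reference gene ids
#'   (possibly empty).
#' @return A list of class `norm_scheme`.
#' @export
norm_scheme <- function(name, reference_genes = character(0)) {
  structure(
    list(name = name, reference_genes = unique(as.character(reference_genes))),
    class = "norm_scheme"
  )
}

#' Per-sample geometric-mean normalization factor
#'
#' `factor[s] = (prod_r Q[r, s])^(1/n_refs)` over the reference genes —
#' the multi-reference normalization factor of the geNorm framework.
#'
#' @param quantities Reference-genes-by-samples matrix of positive
#'   relative quantities (rownames = gene ids).
#' @param reference_genes Genes to combine (default: all rows).
#' @return Named numeric vector of factors, one per sample. Samples
#'   where any reference quantity is missing get `NA` (failed reactions
#'   propagate, never silently drop).
#' @export
geometric_mean_factor <- function(quantities, reference_genes = rownames(quantities)) {
  if (!is.matrix(quantities)) abort_fmt("'quantities' must be a matrix")
  missing <- setdiff(reference_genes, rownames(quantities))
  if (length(missing) > 0) abort_fmt("reference gene '%s' not in table", missing[1])
  q <- quantities[unique(reference_genes), , drop = FALSE]
  bad <- which(!is.na(q) & q <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_fmt(
      "non-positive quantity for gene '%s' in sample '%s'",
      rownames(q)[bad[1, 1]], colnames(q)[bad[1, 2]]
    )
  }
  apply(q, 2, function(col) {
    if (anyNA(col)) NA_real_ else geometric_mean(col)
  })
}

#' Normalize a target gene by a reference scheme
#'
#' Divides the target's per-sample quantity by the scheme's
#' geometric-mean factor; an empty scheme returns the series unchanged.
#' Values stay in relative units unless a calibrator sample is named, in
#' which case the series is rescaled so that the calibrator equals 1.
#'
#' @param target_quantities Named numeric vector (names = sample ids) of
#'   the target gene's relative quantities.
#' @param quantities Reference-genes-by-samples quantity matrix (its
#'   columns must cover the target's samples).
#' @param scheme A [norm_scheme()].
#' @param calibrator Optional sample id to rescale to.
#' @return Tibble `target` (attr), `sample_id`, `value`, `scheme`.
#' @export
normalize_target <- function(target_quantities, quantities, scheme,
                             calibrator = NULL) {
  stopifnot(inherits(scheme, "norm_scheme"))
  samples <- names(target_quantities)
  if (is.null(samples)) abort_fmt("target quantities must be named by sample")
  if (length(scheme$reference_genes) == 0) {
    values <- target_quantities
  } else {
    missing <- setdiff(samples, colnames(quantities))
    if (length(missing) > 0) {
      abort_fmt("sample '%s' absent from the reference table", missing[1])
    }
    factors <- geometric_mean_factor(
      quantities[, samples, drop = FALSE],
      scheme$reference_genes
    )
    values <- target_quantities / factors
  }
  if (!is.null(calibrator)) {
    if (!calibrator %in% samples) abort_fmt("calibrator '%s' not a sample", calibrator)
    values <- values / values[[calibrator]]
  }
  tibble::tibble(
    sample_id = samples,
    value = unname(values),
    scheme = scheme$name
  )
}

#' Compare normalization schemes across target genes
#'
#' Produces the long table behind a scheme-comparison figure: every
#' target under every scheme in every sample. A target gene may not sit
#' in its own reference set.
#'
#' @param quantities Genes-by-samples matrix of relative quantities
#'   covering targets and all reference genes (e.g. built from
#'   [process_qpcr()] output).
#' @param targets Character vector of target gene ids.
#' @param schemes List of [norm_scheme()] objects (include
#'   `norm_scheme("none")` for the non-normalized series).
#' @param calibrator Optional sample id passed to [normalize_target()].
#' @return Long tibble `target`, `scheme`, `sample_id`, `value` with one
#'   row per target x scheme x sample.
#' @export
run_scheme_comparison <- function(quantities, targets, schemes,
                                  calibrator = NULL) {
  missing <- setdiff(targets, rownames(quantities))
  if (length(missing) > 0) abort_fmt("target '%s' not in table", missing[1])
  purrr::map_dfr(targets, function(tg) {
    purrr::map_dfr(schemes, function(sc) {
      stopifnot(inherits(sc, "norm_scheme"))
      if (tg %in% sc$reference_genes) {
        abort_fmt("target '%s' appears in reference set of scheme '%s'", tg, sc$name)
      }
      tv <- quantities[tg, ]
      names(tv) <- colnames(quantities)
      out <- normalize_target(tv, quantities, sc, calibrator)
      tibble::tibble(
        target = tg, scheme = sc$name,
        sample_id = out$sample_id, value = out$value
      )
    })
  })
}

#' Read normalization schemes from a config file
#'
#' One scheme per line, `name: gene1,gene2,...`; an empty gene list
#' (`name:`) is the non-normalized scheme. Blank lines and `#` comments
#' are ignored.
#'
#' @param path Path to the schemes file.
#' @return List of [norm_scheme()] objects.
#' @export
read_schemes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    name <- trimws(parts[1])
    genes <- if (length(parts) < 2 || !nzchar(trimws(parts[2]))) {
      character(0)
    } else {
      trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    }
    norm_scheme(name, genes)
  })
}

#' Line plot of a scheme comparison
#'
#' One panel per target, one line per scheme, samples on the x axis in
#' their input order — the conventional way to eyeball how much the
#' choice of reference genes changes a target's profile.
#'
#' @param comparison Long tibble from [run_scheme_comparison()].
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_scheme_comparison <- function(comparison) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort_fmt("plot_scheme_comparison requires ggplot2")
  }
  comparison$sample_id <- factor(
    comparison$sample_id,
    levels = unique(comparison$sample_id)
  )
  ggplot2::ggplot(
    comparison,
    ggplot2::aes(
      x = .data$sample_id, y = .data$value,
      colour = .data$scheme, group = .data$scheme
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~target, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative expression", colour = "scheme") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
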