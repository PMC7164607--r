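#' Thresholds for the candidate reference-gene filter cascade
#'
#' Bundles the tunable parameters of [run_cascade()]. Defaults encode the
#' published screen: a genotype-group fold change within \[1.0, 1.1\]
#' (i.e. at most a 10% difference between group means), an average
#' expression strictly inside (11, 450) normalized-read units, and a
#' dispersion score — the standard deviation across all libraries divided
#' by the expression in one designated endocarp library — below 0.20 at
#' stage 2 and below 0.11 at stage 3.
#'
#' @param fc_window Length-2 numeric, inclusive fold-change window
#'   (default `c(1.0, 1.1)`).
#' @param fc_mode `"ratio"` (default): the window applies to the
#'   group-mean ratio max/min. `"abs_log2"`: the window applies to
#'   `|log2(mean_a/mean_b)|`, the literal reading of a "log2 difference"
#'   window (which keeps 2- to ~2.14-fold changers; see the vignette for
#'   why ratio is the default for a stability screen).
#' @param expr_min,expr_max Exclusive bounds on the overall mean
#'   expression (defaults 11 and 450).
#' @param stage1_stability_max,stage2_stability_max Strict upper bounds
#'   on the dispersion score at stages 2 and 3 (defaults 0.20 and 0.11).
#' @param reference_library Library id whose expression is the
#'   denominator of the dispersion score (the 'Stoneless' endocarp
#'   library in the original design).
#' @param group_a,group_b Disjoint character vectors of library ids for
#'   the fold-change comparison (e.g. stoneless vs normal libraries).
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(reference_library,
                              group_a,
                              group_b,
                              fc_window = c(1.0, 1.1),
                              fc_mode = c("ratio", "abs_log2"),
                              expr_min = 11,
                              expr_max = 450,
                              stage1_stability_max = 0.20,
                              stage2_stability_max = 0.11) {
  fc_mode <- match.arg(fc_mode)
  if (length(fc_window) != 2 || fc_window[1] > fc_window[2]) {
    abort_fmt("fc_window must be an increasing pair")
  }
  if (!(expr_min < expr_max)) abort_fmt("expr_min must be < expr_max")
  if (!(stage2_stability_max > 0 &&
        stage2_stability_max <= stage1_stability_max)) {
    abort_fmt("need 0 < stage2_stability_max <= stage1_stability_max")
  }
  if (length(intersect(group_a, group_b)) > 0) {
    abort_fmt("fold-change groups overlap")
  }
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort_fmt("fold-change groups must be non-empty")
  }
  structure(
    list(
      fc_window = as.numeric(fc_window), fc_mode = fc_mode,
      expr_min = expr_min, expr_max = expr_max,
      stage1_stability_max = stage1_stability_max,
      stage2_stability_max = stage2_stability_max,
      reference_library = reference_library,
      group_a = group_a, group_b = group_b
    ),
    class = "filter_thresholds"
  )
}

#' Per-gene fold change between two library groups
#'
#' For each gene, the ratio of the larger to the smaller of the two group
#' means, so the value is always >= 1 (or `Inf` when exactly one group
#' mean is 0, `NA` when both are 0).
#'
#' @param x An [expression_matrix()].
#' @param group_a,group_b Disjoint, non-empty character vectors of
#'   library ids.
#' @return Named numeric vector of fold changes, one per gene.
#' @export
group_fold_change <- function(x, group_a, group_b) {
  stopifnot(inherits(x, "expr_matrix"))
  if (length(intersect(group_a, group_b)) > 0) abort_fmt("groups overlap")
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort_fmt("groups must be non-empty")
  }
  missing <- setdiff(c(group_a, group_b), library_ids(x))
  if (length(missing) > 0) abort_fmt("library '%s' not in matrix", missing[1])
  m_a <- rowMeans(x$values[, group_a, drop = FALSE])
  m_b <- rowMeans(x$values[, group_b, drop = FALSE])
  fc <- pmax(m_a, m_b) / pmin(m_a, m_b)
  fc[m_a == 0 & m_b == 0] <- NA_real_ # no signal in either group
  fc
}

#' Genes whose mean expression lies inside an open window
#'
#' @param x An [expression_matrix()].
#' @param genes Character vector of candidate gene ids.
#' @param expr_min,expr_max Exclusive bounds on the overall mean.
#' @return The subset of `genes` with mean strictly inside
#'   `(expr_min, expr_max)`, in input order.
#' @export
expression_window <- function(x, genes = gene_ids(x),
                              expr_min = 11, expr_max = 450) {
  stopifnot(inherits(x, "expr_matrix"))
  missing <- setdiff(genes, gene_ids(x))
  if (length(missing) > 0) abort_fmt("gene '%s' not in matrix", missing[1])
  means <- rowMeans(x$values[genes, , drop = FALSE])
  genes[means > expr_min & means < expr_max]
}

#' Dispersion relative to a reference library
#'
#' The standard deviation of a gene's expression over all libraries
#' divided by its expression in one designated library. Scoring against
#' an endocarp library biases the screen toward genes whose endocarp
#' expression is close to their overall level.
#'
#' @param x An [expression_matrix()].
#' @param gene Gene id, or a vector of gene ids.
#' @param reference_library Library id used as the denominator.
#' @return Named numeric vector of scores; `NA` where the reference value
#'   is 0 (unscorable).
#' @export
endocarp_relative_stability <- function(x, gene = gene_ids(x),
                                        reference_library) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!reference_library %in% library_ids(x)) {
    abort_fmt("reference library '%s' not in matrix", reference_library)
  }
  missing <- setdiff(gene, gene_ids(x))
  if (length(missing) > 0) abort_fmt("gene '%s' not in matrix", missing[1])
  v <- x$values[gene, , drop = FALSE]
  sds <- apply(v, 1, stats::sd)
  ref <- v[, reference_library]
  score <- ifelse(ref > 0, sds / ref, NA_real_)
  names(score) <- gene
  score
}

#' Run the three-stage candidate filter cascade
#'
#' Stage 1 keeps genes whose group fold change falls in the window and
#' whose overall mean lies inside the expression window. Stage 2 keeps
#' stage-1 survivors whose dispersion score (see
#' [endocarp_relative_stability()]) is strictly below
#' `stage1_stability_max`; stage 3 tightens the same score below
#' `stage2_stability_max`. Survivor sets are therefore nested. Genes are
#' ordered by ascending dispersion score within every stage; unscorable
#' genes (reference value 0) never survive stages 2-3.
#'
#' @param x An [expression_matrix()] on the normalized layer the
#'   thresholds were chosen for (RPM or an equivalent per-library
#'   normalization).
#' @param thresholds A [filter_thresholds()] object.
#' @return A list of class `filter_trace`: tibble `scores` (gene_id,
#'   fold_change, mean_expr, stability_score, stage1/2/3 logicals),
#'   ordered survivor character vectors `survivors_stage1/2/3`, and
#'   `counts` (named integer vector).
#' @export
run_cascade <- function(x, thresholds) {
  stopifnot(inherits(x, "expr_matrix"), inherits(thresholds, "filter_thresholds"))
  th <- thresholds
  if (!th$reference_library %in% library_ids(x)) {
    abort_fmt("reference library '%s' not in matrix", th$reference_library)
  }

  genes <- gene_ids(x)
  fc <- group_fold_change(x, th$group_a, th$group_b)
  mean_expr <- rowMeans(x$values)
  score <- endocarp_relative_stability(x, genes, th$reference_library)

  fc_stat <- switch(th$fc_mode,
    ratio = fc,
    abs_log2 = abs(log2(fc))
  )
  in_fc <- !is.na(fc_stat) & is.finite(fc_stat) &
    fc_stat >= th$fc_window[1] & fc_stat <= th$fc_window[2]
  in_expr <- mean_expr > th$expr_min & mean_expr < th$expr_max

  stage1 <- in_fc & in_expr
  stage2 <- stage1 & !is.na(score) & score < th$stage1_stability_max
  stage3 <- stage2 & score < th$stage2_stability_max

  if (!any(stage1)) warning("no genes survive stage 1", call. = FALSE)

  scores <- tibble::tibble(
    gene_id = genes,
    fold_change = unname(fc),
    mean_expr = unname(mean_expr),
    stability_score = unname(score),
    stage1 = unname(stage1),
    stage2 = unname(stage2),
    stage3 = unname(stage3)
  )
  by_score <- function(keep) {
    g <- genes[keep]
    g[order(score[g], is.na(score[g]), g)]
  }
  structure(
    list(
      scores = scores,
      survivors_stage1 = by_score(stage1),
      survivors_stage2 = by_score(stage2),
      survivors_stage3 = by_score(stage3),
      counts = c(
        total = length(genes),
        stage1 = sum(stage1), stage2 = sum(stage2), stage3 = sum(stage3)
      )
    ),
    class = "filter_trace"
  )
}

#' @export
print.filter_trace <- function(x, ...) {
  cat(sprintf(
    "<filter_trace> %d genes -> stage1 %d -> stage2 %d -> stage3 %d\n",
    x$counts["total"], x$counts["stage1"], x$counts["stage2"], x$counts["stage3"]
  ))
  invisible(x)
}

#' Write a filter trace as delimited text
#'
#' @param trace A `filter_trace` from [run_cascade()].
#' @param path Output path.
#' @return `trace`, invisibly.
#' @export
write_filter_trace <- function(trace, path) {
  stopifnot(inherits(trace, "filter_trace"))
  write_delim_auto(trace$scores, path)
  invisible(trace)
}
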