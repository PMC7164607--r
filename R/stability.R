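# Four reference-gene stability algorithms on a genes-by-samples mean-Cq
# matrix, plus the comprehensive geometric-mean-of-ranks combination.
# Ranking deliberately works from raw Cq values with a common assumed
# amplification factor (default 2 per cycle); efficiency-corrected
# quantification lives in the qPCR module and is kept separate.

check_cq_matrix <- function(cq, min_genes = 2, min_samples = 2) {
  if (!is.matrix(cq) || !is.numeric(cq)) abort_fmt("Cq input must be a numeric matrix")
  if (is.null(rownames(cq))) abort_fmt("Cq matrix needs gene ids as rownames")
  if (anyNA(cq)) abort_fmt("Cq matrix has missing cells; collapse/impute first")
  if (nrow(cq) < min_genes) abort_fmt("need >= %d genes", min_genes)
  if (ncol(cq) < min_samples) abort_fmt("need >= %d samples", min_samples)
  invisible(cq)
}

#' Convert a Cq matrix to relative linear quantities
#'
#' `Q[g, s] = E_g ^ (min_s Cq[g, ] - Cq[g, s])`: each gene's
#' highest-expressing sample is set to 1 and every extra cycle divides
#' the quantity by the amplification factor `E_g`.
#'
#' @param cq Genes-by-samples numeric matrix of mean Cq values.
#' @param efficiency Amplification factor per cycle, scalar or one value
#'   per gene; 2 means perfect doubling. (This is the factor itself, not
#'   the percent efficiency: `E = 1 + percent/100`.)
#' @return Matrix of relative quantities with per-gene maximum 1.
#' @export
cq_to_linear <- function(cq, efficiency = 2) {
  check_cq_matrix(cq, min_genes = 1, min_samples = 1)
  if (any(efficiency <= 1)) abort_fmt("amplification factor must exceed 1")
  if (!length(efficiency) %in% c(1L, nrow(cq))) {
    abort_fmt("efficiency must be scalar or one value per gene")
  }
  e <- rep(efficiency, length.out = nrow(cq))
  mins <- apply(cq, 1, min)
  # mins and e (length nrow) recycle down columns, i.e. per gene
  e^(mins - cq)
}

#' Comparative delta-Ct stability
#'
#' For every ordered gene pair, the standard deviation across samples of
#' the Cq difference is computed; a gene's stability value is the mean
#' of these SDs over all partners. Stable genes co-vary with everything
#' (shared input-amount effects cancel in the differences), so lower is
#' more stable.
#'
#' @param cq Genes-by-samples mean-Cq matrix (>= 2 genes).
#' @return Tibble `gene_id`, `value` (cycles), `rank` (1 = most stable,
#'   midpoint ties).
#' @export
delta_ct_stability <- function(cq) {
  check_cq_matrix(cq, min_genes = 2)
  g <- nrow(cq)
  sd_pair <- matrix(0, g, g)
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      s <- stats::sd(cq[i, ] - cq[j, ])
      sd_pair[i, j] <- s
      sd_pair[j, i] <- s
    }
  }
  value <- rowSums(sd_pair) / (g - 1)
  tibble::tibble(
    gene_id = rownames(cq),
    value = value,
    rank = rank_ascending(value)
  )
}

#' BestKeeper dispersion of raw Cq values
#'
#' Per-gene spread of the raw Cq values across samples: the mean
#' absolute deviation from the gene's mean Cq (`mode = "mad"`, the
#' "SD (+/- CP)" figure BestKeeper prints) or the sample standard
#' deviation (`mode = "sd"`). Unlike the other three methods this one
#' does not cancel shared sample effects, by design: it penalizes any
#' raw-Cq variation.
#'
#' @param cq Genes-by-samples mean-Cq matrix.
#' @param mode `"mad"` (default) or `"sd"`.
#' @return Tibble `gene_id`, `value` (cycles), `rank`.
#' @export
bestkeeper_stability <- function(cq, mode = c("mad", "sd")) {
  mode <- match.arg(mode)
  check_cq_matrix(cq, min_genes = 1)
  value <- switch(mode,
    mad = apply(cq, 1, mean_abs_deviation),
    sd = apply(cq, 1, stats::sd)
  )
  tibble::tibble(
    gene_id = rownames(cq),
    value = unname(value),
    rank = rank_ascending(value)
  )
}

#' NormFinder model-based stability
#'
#' Works on log2 relative quantities (see [cq_to_linear()]). Ungrouped:
#' an additive gene + sample model is fitted by row/column means and a
#' gene's stability value is the standard deviation of its residuals,
#' inflated by `sqrt(g/(g-1))` to compensate for the candidate gene
#' itself contributing to the sample-effect estimate. Grouped: an
#' Andersen-style variance decomposition — the absolute intergroup
#' difference of the gene (relative to the group-average shift of all
#' candidates) plus the standard error of its intragroup variation,
#' averaged over groups. Lower is more stable.
#'
#' @param cq Genes-by-samples mean-Cq matrix (>= 3 genes).
#' @param groups Optional character/factor vector of per-sample group
#'   labels (length `ncol(cq)`); each group needs >= 2 samples.
#' @param efficiency Amplification factor per cycle (see
#'   [cq_to_linear()]).
#' @param inflation `"genes"` (default `sqrt(g/(g-1))` correction) or
#'   `"none"` (plain residual SD).
#' @return Tibble `gene_id`, `value`, `rank`; grouped mode adds the
#'   per-group components as attribute `"decomposition"`.
#' @export
normfinder_stability <- function(cq, groups = NULL, efficiency = 2,
                                 inflation = c("genes", "none")) {
  inflation <- match.arg(inflation)
  check_cq_matrix(cq, min_genes = 3)
  g <- nrow(cq)
  y <- log2(cq_to_linear(cq, efficiency))
  infl <- if (inflation == "genes") sqrt(g / (g - 1)) else 1

  if (is.null(groups)) {
    r <- two_way_residuals(y)
    value <- apply(r, 1, function(z) sqrt(sum(z^2) / (length(z) - 1))) * infl
  } else {
    if (length(groups) != ncol(cq)) {
      abort_fmt("'groups' must give one label per sample")
    }
    groups <- as.character(groups)
    sizes <- table(groups)
    if (any(sizes < 2)) {
      abort_fmt("group '%s' has fewer than 2 samples", names(sizes)[sizes < 2][1])
    }
    gene_mean <- rowMeans(y)
    grand <- mean(y)
    per_group <- lapply(unique(groups), function(k) {
      yk <- y[, groups == k, drop = FALSE]
      nk <- ncol(yk)
      # intergroup: gene's shift in this group beyond the common shift
      d <- (rowMeans(yk) - gene_mean) - (mean(yk) - grand)
      # intragroup: residual variance after gene+sample effects within group
      r <- two_way_residuals(yk)
      v <- apply(r, 1, function(z) sum(z^2) / (length(z) - 1)) * infl^2
      list(group = k, n = nk, d = d, var = v)
    })
    value <- Reduce(`+`, lapply(per_group, function(p) {
      abs(p$d) + sqrt(p$var / p$n)
    })) / length(per_group)
    out <- tibble::tibble(
      gene_id = rownames(cq),
      value = unname(value),
      rank = rank_ascending(value)
    )
    attr(out, "decomposition") <- per_group
    return(out)
  }
  tibble::tibble(
    gene_id = rownames(cq),
    value = unname(value),
    rank = rank_ascending(value)
  )
}

# residuals of the additive two-way (gene + sample) model
two_way_residuals <- function(y) {
  y - rowMeans(y) - rep(colMeans(y), each = nrow(y)) + mean(y)
}

#' geNorm expression stability (M value) with stepwise exclusion
#'
#' The pairwise variation `V[g, h]` is the standard deviation across
#' samples of `log2(Q[g, ] / Q[h, ])`; a gene's M value is the mean of
#' its pairwise variations with all other remaining candidates. The gene
#' with the highest M is excluded and M values are recomputed until two
#' genes remain; those two cannot be distinguished by the method and are
#' reported tied at the top. Reported M values are from each gene's last
#' round of inclusion.
#'
#' @param quantities Genes-by-samples matrix of positive relative
#'   quantities (>= 3 genes), e.g. from [cq_to_linear()].
#' @param tie_mode Rank assigned to the two surviving genes:
#'   `"pair"` (default) ties both at 1.5, `"split"` assigns 1 and 2 by
#'   their final M (then gene id).
#' @return Tibble `gene_id`, `m_value`, `rank`, `elimination_round`
#'   (0 for the surviving pair, 1 for the first gene removed, ...).
#'   Attribute `"elimination_order"` lists removed genes in order.
#' @export
genorm_stability <- function(quantities, tie_mode = c("pair", "split")) {
  tie_mode <- match.arg(tie_mode)
  check_cq_matrix(quantities, min_genes = 3)
  if (any(quantities <= 0)) abort_fmt("quantities must be > 0")
  genes <- rownames(quantities)
  ly <- log2(quantities)

  m_of <- function(active) {
    vapply(active, function(g) {
      others <- setdiff(active, g)
      mean(vapply(
        others,
        function(h) stats::sd(ly[g, ] - ly[h, ]),
        numeric(1)
      ))
    }, numeric(1))
  }

  active <- genes
  m_last <- stats::setNames(rep(NA_real_, length(genes)), genes)
  eliminated <- character(0)
  while (length(active) > 2) {
    m <- m_of(active)
    worst <- max(m)
    # tie at the maximum: remove the lexicographically last gene id
    victim <- max(names(m)[m == worst])
    m_last[victim] <- m[victim]
    eliminated <- c(eliminated, victim)
    active <- setdiff(active, victim)
  }
  m_final <- m_of(active)
  m_last[active] <- m_final

  round_of <- stats::setNames(rep(0L, length(genes)), genes)
  round_of[eliminated] <- seq_along(eliminated)

  n <- length(genes)
  rank <- stats::setNames(rep(NA_real_, n), genes)
  rank[eliminated] <- n - round_of[eliminated] + 1L
  if (tie_mode == "pair") {
    rank[active] <- 1.5
  } else {
    ord <- active[order(m_final[active], active)]
    rank[ord] <- c(1, 2)
  }

  out <- tibble::tibble(
    gene_id = genes,
    m_value = unname(m_last[genes]),
    rank = unname(rank[genes]),
    elimination_round = unname(round_of[genes])
  )
  attr(out, "elimination_order") <- eliminated
  out
}

#' geNorm pairwise variation V(k/k+1)
#'
#' The standard deviation across samples of the log2 ratio of the
#' normalization factors (geometric means) built from the top `k` versus
#' the top `k + 1` genes of the geNorm ranking. Small V(k/k+1) means the
#' (k+1)-th gene adds little, the classical guide to how many reference
#' genes to use; this function computes V and leaves the judgement to
#' the analyst.
#'
#' @param quantities Genes-by-samples matrix of positive quantities.
#' @param k Number of top genes in the smaller factor (2 <= k < genes).
#' @param ranking Optional [genorm_stability()] result to reuse;
#'   computed afresh otherwise.
#' @return The pairwise variation V(k/k+1), a single number.
#' @export
genorm_pairwise_variation <- function(quantities, k, ranking = NULL) {
  check_cq_matrix(quantities, min_genes = 3)
  if (!is_count(k) || k < 2 || k + 1 > nrow(quantities)) {
    abort_fmt("k must satisfy 2 <= k <= genes - 1")
  }
  if (is.null(ranking)) ranking <- genorm_stability(quantities)
  # deterministic top order: ascending rank, then M, then gene id
  ord <- ranking$gene_id[order(ranking$rank, ranking$m_value, ranking$gene_id)]
  nf <- function(gs) {
    apply(quantities[gs, , drop = FALSE], 2, geometric_mean)
  }
  stats::sd(log2(nf(ord[seq_len(k)]) / nf(ord[seq_len(k + 1)])))
}

#' Comprehensive rank: geometric mean of the four method ranks
#'
#' The RefFinder-style combination: each gene's ranks under delta-Ct,
#' BestKeeper, NormFinder and geNorm are combined by their geometric
#' mean, and genes are ordered by that mean. Ties are broken by the
#' delta-Ct stability value, then gene id.
#'
#' @param ranks Data frame with columns `gene_id`, `rank_delta_ct`,
#'   `rank_bestkeeper`, `rank_normfinder`, `rank_genorm`, and (for
#'   tie-breaking) `value_delta_ct`.
#' @return Tibble `gene_id`, `comprehensive_geomean`,
#'   `comprehensive_rank` (a strict 1..n permutation).
#' @export
comprehensive_rank <- function(ranks) {
  needed <- c(
    "gene_id", "rank_delta_ct", "rank_bestkeeper",
    "rank_normfinder", "rank_genorm"
  )
  missing <- setdiff(needed, names(ranks))
  if (length(missing) > 0) {
    abort_fmt("missing method rank column '%s'", missing[1])
  }
  rk <- as.matrix(ranks[c(
    "rank_delta_ct", "rank_bestkeeper", "rank_normfinder", "rank_genorm"
  )])
  if (anyNA(rk)) abort_fmt("every gene needs all four method ranks")
  geomean <- apply(rk, 1, geometric_mean)
  tiebreak <- if ("value_delta_ct" %in% names(ranks)) {
    ranks$value_delta_ct
  } else {
    rep(0, nrow(ranks))
  }
  ord <- order(geomean, tiebreak, ranks$gene_id)
  final <- integer(nrow(ranks))
  final[ord] <- seq_len(nrow(ranks))
  tibble::tibble(
    gene_id = ranks$gene_id,
    comprehensive_geomean = geomean,
    comprehensive_rank = final
  )
}

#' Full stability report for a mean-Cq matrix
#'
#' Runs all four stability algorithms and the comprehensive combination.
#' Per the usual RefFinder practice the input is the raw mean-Cq matrix
#' and a common amplification factor (default perfect doubling) is
#' assumed; supply per-gene factors for a sensitivity analysis.
#'
#' @param cq Genes-by-samples mean-Cq matrix (>= 3 genes, >= 3 samples,
#'   no missing cells).
#' @param groups Optional per-sample group labels for grouped
#'   NormFinder.
#' @param efficiency Amplification factor(s) per cycle, scalar or per
#'   gene (2 = 100% efficiency).
#' @param bestkeeper_mode `"mad"` or `"sd"` (see
#'   [bestkeeper_stability()]).
#' @param genorm_tie `"pair"` or `"split"` (see [genorm_stability()]).
#' @return Tibble with one row per gene: each method's stability value
#'   and rank, `comprehensive_geomean` and `comprehensive_rank`, sorted
#'   by comprehensive rank.
#' @export
stability_report <- function(cq, groups = NULL, efficiency = 2,
                             bestkeeper_mode = c("mad", "sd"),
                             genorm_tie = c("pair", "split")) {
  bestkeeper_mode <- match.arg(bestkeeper_mode)
  genorm_tie <- match.arg(genorm_tie)
  check_cq_matrix(cq, min_genes = 3, min_samples = 3)

  dct <- delta_ct_stability(cq)
  bk <- bestkeeper_stability(cq, bestkeeper_mode)
  nf <- normfinder_stability(cq, groups, efficiency)
  gn <- genorm_stability(cq_to_linear(cq, efficiency), genorm_tie)

  ranks <- tibble::tibble(
    gene_id = dct$gene_id,
    value_delta_ct = dct$value, rank_delta_ct = dct$rank,
    value_bestkeeper = bk$value, rank_bestkeeper = bk$rank,
    value_normfinder = nf$value, rank_normfinder = nf$rank,
    value_genorm_m = gn$m_value, rank_genorm = gn$rank
  )
  comp <- comprehensive_rank(ranks)
  dplyr::left_join(ranks, comp, by = "gene_id") |>
    dplyr::arrange(.data$comprehensive_rank)
}

#' Write a stability report as delimited text
#'
#' @param report Tibble from [stability_report()].
#' @param path Output path.
#' @return `report`, invisibly.
#' @export
write_stability_report <- function(report, path) {
  write_delim_auto(report, path)
  invisible(report)
}
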