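#' Specification for the qPCR Cq simulator
#'
#' Defines a synthetic qPCR experiment over a small sample panel
#' (default: a seven-stage fruit developmental series DS1-DS7 plus two
#' 'Stoneless' and two normal endocarp samples). Each gene has a true
#' per-gene noise SD (cycles) — the quantity the stability algorithms
#' should recover — and an amplification factor that fixes its
#' standard-curve slope. All genes share per-sample effects (default SD
#' 0.8 cycles) mimicking differences in RNA input amount, which is
#' exactly the variation reference-gene normalization exists to remove.
#' Technical triplicates get replicate noise, and occasional outlier
#' replicates are injected with a shift large enough (> 0.5 cycles) to
#' trigger the discard rule.
#'
#' @param genes Tibble with columns `gene_id`, `noise_sd` (cycles),
#'   and optionally `efficiency` (amplification factor per cycle,
#'   default 2) and `base_cq` (Cq of the undiluted standard, default
#'   drawn in 20-26).
#' @param samples Character vector of sample ids.
#' @param sample_effect_sd Shared per-sample shift SD in cycles.
#' @param replicate_sd Technical replicate SD in cycles.
#' @param n_replicates Technical replicates per reaction (<= 3).
#' @param outlier_probability Per-reaction probability that one
#'   replicate is shifted by `outlier_shift`.
#' @param outlier_shift Injected outlier displacement in cycles (must
#'   exceed the 0.5-cycle discard distance).
#' @param bias_cq Optional genes-by-samples matrix of planted Cq offsets
#'   (cycles) for differentially expressed target genes; 0 = flat.
#' @param dilution_points Number of points in each standard-curve
#'   series.
#' @param dilution_fold Fold change between successive dilutions
#'   (default 5).
#' @param dilution_replicate_sd Replicate SD for the dilution series
#'   (0 gives noiseless curves).
#' @param seed Integer seed.
#' @return A list of class `cq_sim_spec`.
#' @export
cq_sim_spec <- function(genes,
                        samples = c(
                          paste0("DS", 1:7),
                          "Stendo1", "Stendo2", "Cendo1", "Cendo2"
                        ),
                        sample_effect_sd = 0.8,
                        replicate_sd = 0.15,
                        n_replicates = 3,
                        outlier_probability = 0.02,
                        outlier_shift = 1.5,
                        bias_cq = NULL,
                        dilution_points = 5,
                        dilution_fold = 5,
                        dilution_replicate_sd = 0,
                        seed = 1L) {
  genes <- tibble::as_tibble(genes)
  if (!all(c("gene_id", "noise_sd") %in% names(genes))) {
    abort_fmt("'genes' needs columns gene_id and noise_sd")
  }
  if (!"efficiency" %in% names(genes)) genes$efficiency <- 2
  if (any(genes$efficiency <= 1)) abort_fmt("amplification factors must exceed 1")
  if (outlier_probability < 0 || outlier_probability > 1) {
    abort_fmt("outlier_probability must lie in [0,1]")
  }
  if (outlier_shift <= 0.5) {
    abort_fmt("outlier_shift must exceed the 0.5-cycle discard distance")
  }
  if (dilution_fold <= 1) abort_fmt("dilution_fold must exceed 1")
  if (!is_count(dilution_points) || dilution_points < 3) {
    abort_fmt("need >= 3 dilution points")
  }
  if (!is_count(n_replicates) || n_replicates > 3) {
    abort_fmt("n_replicates must be 1, 2 or 3")
  }
  if (!is.null(bias_cq)) {
    stopifnot(
      is.matrix(bias_cq),
      nrow(bias_cq) == nrow(genes), ncol(bias_cq) == length(samples)
    )
  }
  structure(
    list(
      genes = genes, samples = samples,
      sample_effect_sd = sample_effect_sd,
      replicate_sd = replicate_sd, n_replicates = as.integer(n_replicates),
      outlier_probability = outlier_probability,
      outlier_shift = outlier_shift,
      bias_cq = bias_cq,
      dilution_points = as.integer(dilution_points),
      dilution_fold = dilution_fold,
      dilution_replicate_sd = dilution_replicate_sd,
      seed = as.integer(seed)
    ),
    class = "cq_sim_spec"
  )
}

#' Simulate a qPCR experiment with known ground truth
#'
#' Each reaction's true Cq is `base_cq[g] + bias_cq[g, s] +
#' sample_effect[s] + gene_noise[g, s]`; technical replicates add
#' replicate noise, and with probability `outlier_probability` one
#' replicate is displaced by `outlier_shift` cycles (random sign).
#' Standard-curve series are generated from the same per-gene curves
#' (`slope = -1 / log10(efficiency)`), so fitting them recovers the true
#' parameters.
#'
#' @param spec A [cq_sim_spec()].
#' @return List with `cq_long` (tibble `sample_id`, `gene_id`,
#'   `replicate`, `cq`), `dilutions` (tibble `gene_id`,
#'   `relative_input`, `replicate`, `cq`) and `truth` (list: `genes`
#'   tibble with `base_cq`, `slope`, `noise_sd`, `efficiency`;
#'   `sample_effects`; `true_cq` matrix before replicate noise;
#'   `n_outliers_injected`).
#' @export
simulate_cq <- function(spec) {
  stopifnot(inherits(spec, "cq_sim_spec"))
  withr::with_seed(spec$seed, {
    genes <- spec$genes
    g <- nrow(genes)
    s <- length(spec$samples)
    if (!"base_cq" %in% names(genes)) {
      genes$base_cq <- stats::runif(g, 20, 26)
    }
    genes$slope <- -1 / log10(genes$efficiency)

    u <- stats::rnorm(s, 0, spec$sample_effect_sd)
    noise <- matrix(stats::rnorm(g * s, 0, genes$noise_sd), nrow = g)
    bias <- if (is.null(spec$bias_cq)) 0 else spec$bias_cq
    true_cq <- genes$base_cq + bias +
      matrix(u, g, s, byrow = TRUE) + noise
    dimnames(true_cq) <- list(genes$gene_id, spec$samples)

    nr <- spec$n_replicates
    cq_long <- tidyr::expand_grid(
      sample_id = spec$samples,
      gene_id = genes$gene_id,
      replicate = seq_len(nr)
    )
    cq_long$cq <- true_cq[cbind(cq_long$gene_id, cq_long$sample_id)] +
      stats::rnorm(nrow(cq_long), 0, spec$replicate_sd)

    # outlier injection: per reaction, displace one random replicate
    n_out <- 0L
    if (spec$outlier_probability > 0 && nr >= 2) {
      reactions <- tidyr::expand_grid(
        sample_id = spec$samples, gene_id = genes$gene_id
      )
      hit <- stats::runif(nrow(reactions)) < spec$outlier_probability
      n_out <- sum(hit)
      if (n_out > 0) {
        which_rep <- sample(nr, n_out, replace = TRUE)
        shift <- sample(c(-1, 1), n_out, replace = TRUE) * spec$outlier_shift
        key <- paste(reactions$sample_id[hit], reactions$gene_id[hit], which_rep)
        all_key <- paste(cq_long$sample_id, cq_long$gene_id, cq_long$replicate)
        cq_long$cq[match(key, all_key)] <-
          cq_long$cq[match(key, all_key)] + shift
      }
    }

    dilutions <- tidyr::expand_grid(
      gene_id = genes$gene_id,
      relative_input = spec$dilution_fold^(-(seq_len(spec$dilution_points) - 1)),
      replicate = seq_len(nr)
    ) |>
      dplyr::left_join(
        genes[c("gene_id", "base_cq", "slope")],
        by = "gene_id"
      ) |>
      dplyr::mutate(
        cq = .data$base_cq + .data$slope * log10(.data$relative_input) +
          stats::rnorm(dplyr::n(), 0, spec$dilution_replicate_sd)
      ) |>
      dplyr::select("gene_id", "relative_input", "replicate", "cq")

    list(
      cq_long = cq_long[c("sample_id", "gene_id", "replicate", "cq")],
      dilutions = dilutions,
      truth = list(
        genes = genes,
        sample_effects = stats::setNames(u, spec$samples),
        true_cq = true_cq,
        n_outliers_injected = n_out
      )
    )
  })
}
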