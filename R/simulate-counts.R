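#' The 20-library plum study design
#'
#' The library layout the count simulator emulates: two normal-stone
#' cultivars and two trees of a 'Stoneless' cultivar, each contributing
#' four early whole-ovary/whole-fruit timepoints plus one endocarp
#' library, for 20 libraries in total. Endocarp libraries sit at
#' positions 5, 10, 15 and 20; `L20` (the second 'Stoneless' tree's
#' endocarp) is the conventional reference library for the dispersion
#' score of the filter cascade.
#'
#' @return Tibble with columns `library_id`, `cultivar`, `tree`,
#'   `tissue`, `timepoint`, `genotype_group`.
#' @export
plum_library_design <- function() {
  trees <- tibble::tibble(
    cultivar = c("CacanskaLepotica", "ReineClaude", "Stoneless", "Stoneless"),
    tree = c("CL1", "RC1", "ST1", "ST2"),
    genotype_group = c("normal", "normal", "stoneless", "stoneless")
  )
  per_tree <- tibble::tibble(
    tissue = c("ovary", "whole_fruit", "whole_fruit", "whole_fruit", "endocarp"),
    timepoint = c("T1", "T2", "T3", "T4", "T4")
  )
  design <- tidyr::expand_grid(trees, idx = seq_len(nrow(per_tree))) |>
    dplyr::mutate(
      tissue = per_tree$tissue[.data$idx],
      timepoint = per_tree$timepoint[.data$idx],
      library_id = sprintf("L%02d", dplyr::row_number())
    ) |>
    dplyr::select(
      "library_id", "cultivar", "tree", "tissue", "timepoint",
      "genotype_group"
    )
  design
}

#' Specification for the count-matrix simulator
#'
#' Defines a synthetic RNA-seq experiment with three planted gene
#' classes: `stable` genes (no tissue bias, tight negative-binomial
#' dispersion — the kind of gene the filter cascade should recover),
#' `tissue_biased` genes (shifted up or down in endocarp libraries by a
#' log2 bias drawn from `endocarp_log2_bias`), and `noisy` genes (no
#' systematic bias but high dispersion). Defaults give library sizes of
#' 5-20 million reads and baseline means of 10-500 normalized-read
#' units, straddling the (11, 450) expression window so the cascade has
#' genes to reject on every criterion.
#'
#' @param n_genes Total genes to simulate.
#' @param library_design Library metadata tibble (default
#'   [plum_library_design()]).
#' @param stable_fraction,tissue_biased_fraction Fractions of genes in
#'   the stable and tissue-biased classes (rest are noisy); must sum to
#'   at most 1.
#' @param endocarp_log2_bias Length-2 range of absolute log2 endocarp
#'   bias for tissue-biased genes (sign drawn at random).
#' @param baseline_mean Length-2 range (log-uniform draw) of baseline
#'   expression for noisy/biased genes, in normalized-read units.
#' @param stable_baseline Length-2 range for stable genes, kept inside
#'   the default expression window.
#' @param dispersion Negative-binomial dispersion of noisy genes.
#' @param biased_dispersion,stable_dispersion Dispersions of the other
#'   two classes.
#' @param library_size Length-2 range of total mapped reads per library.
#' @param seed Integer seed; the simulation is fully reproducible from
#'   the spec.
#' @return A list of class `count_sim_spec`.
#' @export
count_sim_spec <- function(n_genes = 500,
                           library_design = plum_library_design(),
                           stable_fraction = 0.2,
                           tissue_biased_fraction = 0.3,
                           endocarp_log2_bias = c(1, 3),
                           baseline_mean = c(10, 500),
                           stable_baseline = c(50, 400),
                           dispersion = 0.3,
                           biased_dispersion = 0.02,
                           stable_dispersion = 0.002,
                           library_size = c(5e6, 2e7),
                           seed = 1L) {
  if (!is_count(n_genes)) abort_fmt("n_genes must be a positive integer")
  fr <- c(stable_fraction, tissue_biased_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    abort_fmt("class fractions must lie in [0,1] and sum to <= 1")
  }
  if (dispersion <= 0 || biased_dispersion <= 0 || stable_dispersion <= 0) {
    abort_fmt("dispersions must be > 0")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      library_design = tibble::as_tibble(library_design),
      stable_fraction = stable_fraction,
      tissue_biased_fraction = tissue_biased_fraction,
      endocarp_log2_bias = endocarp_log2_bias,
      baseline_mean = baseline_mean,
      stable_baseline = stable_baseline,
      dispersion = dispersion,
      biased_dispersion = biased_dispersion,
      stable_dispersion = stable_dispersion,
      library_size = library_size,
      seed = as.integer(seed)
    ),
    class = "count_sim_spec"
  )
}

#' Simulate an RNA-seq count matrix with known ground truth
#'
#' Counts follow a negative-binomial model,
#' `mean[g, l] = library_size[l] / 1e6 * baseline[g] * 2^(bias[g] *
#' endocarp[l])`, with class-specific dispersion. Stable genes have zero
#' bias and tight dispersion; the noise model is the standard gamma-
#' Poisson used for bulk RNA-seq counts.
#'
#' @param spec A [count_sim_spec()].
#' @return List with `matrix` (an [expression_matrix()], raw-counts
#'   layer, metadata including simulated `total_mapped_reads`) and
#'   `truth` (tibble `gene_id`, `class`, `baseline`,
#'   `endocarp_log2_bias`, `dispersion`).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "count_sim_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_genes
    design <- spec$library_design
    n_lib <- nrow(design)
    endocarp <- as.numeric(design$tissue == "endocarp")

    n_stable <- round(n * spec$stable_fraction)
    n_biased <- round(n * spec$tissue_biased_fraction)
    class <- sample(rep(
      c("stable", "tissue_biased", "noisy"),
      c(n_stable, n_biased, n - n_stable - n_biased)
    ))
    gene_id <- sprintf("G%04d", seq_len(n))

    log_unif <- function(k, range) exp(stats::runif(k, log(range[1]), log(range[2])))
    baseline <- numeric(n)
    baseline[class == "stable"] <-
      log_unif(sum(class == "stable"), spec$stable_baseline)
    baseline[class != "stable"] <-
      log_unif(sum(class != "stable"), spec$baseline_mean)

    bias <- numeric(n)
    nb <- sum(class == "tissue_biased")
    bias[class == "tissue_biased"] <-
      sample(c(-1, 1), nb, replace = TRUE) *
        stats::runif(nb, spec$endocarp_log2_bias[1], spec$endocarp_log2_bias[2])

    disp <- c(
      stable = spec$stable_dispersion,
      tissue_biased = spec$biased_dispersion,
      noisy = spec$dispersion
    )[class]

    lib_size <- round(stats::runif(
      n_lib, spec$library_size[1], spec$library_size[2]
    ))

    mu <- outer(baseline, lib_size / 1e6) * 2^(outer(bias, endocarp))
    counts <- matrix(
      stats::rnbinom(n * n_lib, mu = mu, size = 1 / disp),
      nrow = n,
      dimnames = list(gene_id, design$library_id)
    )

    meta <- design
    meta$total_mapped_reads <- lib_size
    list(
      matrix = expression_matrix(counts, meta, layer = "raw_counts"),
      truth = tibble::tibble(
        gene_id = gene_id,
        class = class,
        baseline = baseline,
        endocarp_log2_bias = bias,
        dispersion = unname(disp)
      )
    )
  })
}
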