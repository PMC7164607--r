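#' Write the canonical synthetic fixture suite
#'
#' Generates one small, fully reproducible dataset exercising every
#' pipeline stage and writes it as plain text: a 20-library count matrix
#' with planted gene classes (for the filter cascade), a qPCR experiment
#' over 14 genes — nine stable reference candidates (`P1`-`P9`), one
#' high-noise `UBQ`-like gene, and four targets (`PT1`-`PT4`) with
#' planted endocarp/stage expression profiles — plus fivefold dilution
#' series and a normalization-schemes file.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed; the same seed always yields byte-identical
#'   files.
#' @param n_genes Genes in the count matrix.
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 42L, n_genes = 120L) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_fmt("cannot create directory '%s'", out_dir)
  }
  if (file.access(out_dir, mode = 2) != 0) {
    abort_fmt("directory '%s' is not writable", out_dir)
  }

  counts <- simulate_counts(count_sim_spec(n_genes = n_genes, seed = seed))
  cq <- simulate_cq(fixture_cq_spec(seed = seed))

  paths <- c(
    counts = file.path(out_dir, "counts.tsv"),
    meta = file.path(out_dir, "library_meta.tsv"),
    counts_truth = file.path(out_dir, "counts_truth.tsv"),
    cq = file.path(out_dir, "cq_long.csv"),
    dilutions = file.path(out_dir, "dilutions.csv"),
    cq_truth = file.path(out_dir, "cq_truth.tsv"),
    schemes = file.path(out_dir, "schemes.cfg")
  )
  write_expression_matrix(counts$matrix, paths["counts"], paths["meta"])
  write_delim_auto(counts$truth, paths["counts_truth"])
  write_delim_auto(cq$cq_long, paths["cq"])
  write_delim_auto(cq$dilutions, paths["dilutions"])
  write_delim_auto(cq$truth$genes, paths["cq_truth"])
  writeLines(
    c(
      "# normalization schemes: name: comma-separated reference genes",
      "none:",
      "UBQ: UBQ",
      "all_four: P2,P3,P7,UBQ",
      "top3: P2,P3,P7",
      "no_P2: P3,P7,UBQ"
    ),
    paths["schemes"]
  )
  invisible(paths)
}

# the fixture qPCR design: 9 tight reference candidates, one drifting
# UBQ-like gene, and 4 targets with planted profiles over the 11-sample
# panel (DS1-DS7 + 4 endocarp samples)
fixture_cq_spec <- function(seed = 42L) {
  genes <- tibble::tibble(
    gene_id = c(paste0("P", 1:9), "UBQ", paste0("PT", 1:4)),
    noise_sd = c(
      stats::setNames(seq(0.10, 0.26, length.out = 9), NULL),
      1.0,
      rep(0.10, 4)
    ),
    efficiency = 2
  )
  samples <- c(paste0("DS", 1:7), "Stendo1", "Stendo2", "Cendo1", "Cendo2")
  endo <- grepl("endo", samples)
  # planted target profiles, in cycles (negative = higher expression)
  bias <- matrix(0, nrow(genes), length(samples),
    dimnames = list(genes$gene_id, samples)
  )
  bias["PT1", ] <- ifelse(endo, -2, 0) # up in endocarp
  bias["PT2", ] <- ifelse(samples == "DS4", -1.5, 0) # stage peak
  bias["PT3", ] <- ifelse(startsWith(samples, "Cendo"), -2.5, 0) # normal endocarp only
  bias["PT4", ] <- seq(0, -2, length.out = length(samples)) # rising profile
  cq_sim_spec(
    genes = genes, samples = samples, bias_cq = bias, seed = seed
  )
}
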