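# refstab

Discovery and validation of reference (housekeeping) genes for
quantitative expression studies.

qPCR reports a target gene's expression relative to one or more reference
genes, so an unstable reference silently corrupts every normalized result.
In developing stone fruit — the system this pipeline was designed around —
several classical references (actin, tubulin, GAPDH, polyubiquitin) vary
up to 8-fold across early-fruit libraries and diverge sharply in endocarp
(stone) tissue. `refstab` implements the transcriptome-mining remedy end
to end:

1. **Candidate screening** from an RNA-seq gene-by-library matrix with a
   three-stage filter cascade: a genotype-group fold-change window
   (`fc = max(m_A, m_B) / min(m_A, m_B) ∈ [1.0, 1.1]`), an expression
   window (mean strictly inside (11, 450) normalized-read units), and a
   dispersion screen `SD(all libraries) / value(endocarp reference
   library)` below 0.20 then 0.11.
2. **qPCR validation**: triplicate collapsing with the 0.5-cycle
   outlier-discard rule, standard curves from fivefold dilution series
   (`Cq = b + m·log10(input)`, efficiency `100·(10^(−1/m) − 1)` %), and
   stability ranking of the candidates with four established algorithms —
   comparative delta-Ct, BestKeeper, NormFinder and geNorm (M value with
   stepwise exclusion) — combined into a RefFinder-style comprehensive
   rank (geometric mean of the four method ranks).
3. **Normalization** of target genes by single- or multi-reference
   schemes via per-sample geometric-mean factors.
4. **Synthetic data** with known ground truth (negative-binomial counts
   over a 20-library design; Cq experiments with shared sample effects
   and planted per-gene noise) so the whole pipeline is testable offline.

See `vignettes/reference-gene-stability.Rmd` for the models, estimator
choices and the generator's design.

## Worked example

Screen candidates on a simulated 20-library experiment, then rank a
10-gene qPCR validation panel:

```r
library(refstab)

sim <- simulate_counts(count_sim_spec(n_genes = 500, seed = 2024))
rpm <- to_rpm(sim$matrix, "metadata")
meta <- rpm$libraries
th <- filter_thresholds(
  reference_library = "L20",
  group_a = meta$library_id[meta$genotype_group == "stoneless"],
  group_b = meta$library_id[meta$genotype_group == "normal"]
)
run_cascade(rpm, th)
#> <filter_trace> 500 genes -> stage1 272 -> stage2 102 -> stage3 100
```

272 genes pass the fold-change and expression windows, 102 the 20 %
dispersion screen, and 100 the final 11 % screen — in this simulation,
exactly the planted stable class. Validation on the canonical qPCR
fixture (nine tight candidates `P1`–`P9` plus a drifting `UBQ`-like
gene over 11 samples):

```r
paths <- make_fixture_suite(tempdir(), seed = 42)
cq <- readr::read_csv(paths[["cq"]], show_col_types = FALSE)
cm <- cq_matrix_from_collapsed(collapse_cq_table(cq),
                               genes = c(paste0("P", 1:9), "UBQ"))
stability_report(cm)
#>   gene_id value_delta_ct value_genorm_m comprehensive_geomean comprehensive_rank
#> 1      P4          0.315          0.243                  2.30                  1
#> 2      P1          0.318          0.138                  2.45                  2
#> 3      P2          0.326          0.255                  2.51                  3
#> 4      P3          0.322          0.138                  3.46                  4
#> ...
#> 10    UBQ          0.814          0.814                 10.00                 10
```

Stability values are in cycles (delta-Ct, BestKeeper) or log2 units
(NormFinder, geNorm M); lower is more stable, and the drifting UBQ-like
gene lands last under every method. Standard curves fitted from the
fixture's noiseless fivefold dilution series recover the generating
parameters exactly:

```r
fit_standard_curves(readr::read_csv(paths[["dilutions"]], show_col_types = FALSE))
#>   gene_id  slope intercept r_squared efficiency_percent n_points
#> 1      P1 -3.322     25.49         1                100        5
#> 2      P2 -3.322     25.62         1                100        5
#> ...
```

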