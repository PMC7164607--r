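---
title: "Discovering and validating reference genes with refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and validating reference genes with refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Quantitative expression studies — qPCR above all — report a target gene's
expression *relative to* one or more reference ("housekeeping") genes. If a
reference gene itself varies across the tissues, timepoints or genotypes
under study, every normalized result inherits that variation. Classical
references (actin, tubulin, GAPDH, polyubiquitin) were chosen long before
transcriptome-wide data existed, and in many systems they are demonstrably
unstable; in developing stone fruit, for instance, several of them diverge
sharply between endocarp (the tissue that lignifies into the stone) and the
surrounding whole fruit.

`refstab` implements the now-standard remedy as a reusable pipeline:

1. **mine an existing RNA-seq experiment** for genes that are empirically
   stable across precisely the conditions of interest (a three-stage filter
   cascade over a gene-by-library matrix);
2. **validate candidates by qPCR** — collapse technical replicates, fit
   serial-dilution standard curves, and rank candidate stability with four
   established algorithms (comparative delta-Ct, BestKeeper, NormFinder,
   geNorm) combined into a comprehensive geometric-mean rank;
3. **normalize target genes** against the winning single- or
   multi-reference schemes;
4. **simulate** count matrices and qPCR experiments with known ground truth
   so that every stage of the pipeline is testable without any external
   download.

## The filter cascade

The cascade operates on a normalized gene-by-library matrix (reads per
million, or any equivalent per-library normalization — thresholds apply to
whichever layer is loaded). Its canonical design compares a mutant genotype
group against normal cultivars over a 20-library early-fruit panel, with
one designated endocarp library as the dispersion reference. Three nested
stages:

* **Stage 1 — fold-change and expression windows.** For each gene the two
  genotype-group means $m_A$, $m_B$ give a fold change
  $\mathrm{fc} = \max(m_A, m_B) / \min(m_A, m_B) \ge 1$; genes are kept
  when $\mathrm{fc} \in [1.0, 1.1]$ (at most a 10 % group difference) *and*
  the overall mean lies strictly inside the expression window
  $(11, 450)$ — high enough to detect reliably, low enough that qPCR input
  need not be diluted.
* **Stage 2 / Stage 3 — dispersion relative to an endocarp library.** The
  score $s_g = \mathrm{SD}(x_{g\cdot}) / x_{g,\mathrm{ref}}$ divides the
  standard deviation over *all* libraries by the gene's value in one
  endocarp library, deliberately biasing the screen toward genes whose
  endocarp expression matches their overall level. Stage 2 keeps
  $s_g < 0.20$, stage 3 keeps $s_g < 0.11$ (strict inequalities).

Two interpretation decisions were genuinely open and are worth recording.
The fold-change window is sometimes described as a window on "log2
differences" between 1.0 and 1.1; read literally that would *keep* genes
changing 2-fold to 2.14-fold and discard the flat ones, which contradicts
the purpose of a stability screen. The default therefore treats the window
as a bound on the fold-change **ratio** itself (`fc_mode = "ratio"`), and
the literal reading remains available as `fc_mode = "abs_log2"`. Similarly
an expression criterion phrased "greater than 11 **or** less than 450"
excludes nothing as a joint exclusion; it is implemented as the evident
conjunction with exclusive bounds. Ties exactly at a dispersion threshold
are excluded (the screen says "less than").

`run_cascade()` returns full per-gene traceability (every score plus
per-stage membership), guarantees stage nesting, orders survivors by
ascending dispersion score, and is invariant to gene order. Genes
unscorable at the reference library (value 0) never survive stages 2–3.

## qPCR processing

**Replicate collapsing.** Reactions are run in technical triplicates. If
exactly one replicate lies more than 0.5 cycles from *both* others it is
discarded and the remaining two are averaged; if all three are mutually
more than 0.5 cycles apart the reaction is marked *failed* and propagates
as a missing value (never silently dropped). With two replicates the rule
cannot identify an outlier — both are averaged and flagged `"unguarded"`.
The rule is permutation-invariant and is tested against an exhaustive
enumeration of triples.

**Standard curves.** A fivefold serial dilution of one RNA gives, for each
primer pair, points $(\log_{10} x_i, \mathrm{Cq}_i)$ fitted by ordinary
least squares: $\mathrm{Cq} = b + m \log_{10} x$. The abscissa convention
puts the undiluted sample at relative input $x = 1$. Amplification
efficiency follows from the slope,

$$E\,[\%] = 100\,(10^{-1/m} - 1),$$

so $m = -3.32$ cycles per decade is perfect doubling (100 %). Quantities
are recovered by inverting the curve, $Q = 10^{(\mathrm{Cq} - b)/m}$,
expressed relative to the undiluted standard. A curve needs at least three
distinct dilution points; fewer, or zero variance in the inputs, is a hard
error rather than a degenerate fit.

**Efficiency and ranking are kept separate.** Stability ranking (next
section) deliberately consumes the raw mean-Cq matrix with a common
assumed amplification factor of 2 per cycle — the convention of the
RefFinder-style comprehensive comparison — while efficiency-corrected
quantification remains available for the normalization stage. Per-gene
factors can be passed to the ranking functions for sensitivity analysis.

## The four stability algorithms

All four consume a complete genes × samples mean-Cq matrix (≥ 3 genes;
columns with failed reactions should be dropped first). Lower values mean
more stable, and each method returns midpoint-tied ranks.

* **Comparative delta-Ct.** For each gene pair the SD across samples of
  the Cq difference; a gene's value is the mean SD over all partners.
  Shared sample effects (RNA input amount) cancel in the differences.
* **BestKeeper.** Dispersion of the raw Cq values themselves; the default
  is the mean absolute deviation from the gene's mean (the "SD (± CP)"
  figure the original BestKeeper spreadsheet prints), with the sample SD
  as an option. This is the one method that does **not** cancel shared
  sample effects — an intended asymmetry, since it penalizes any raw-Cq
  drift, and the package's tests document it.
* **NormFinder.** On $y = \log_2 Q$ (with $Q$ from the Cq→linear
  transform), the ungrouped estimator fits the additive model
  $y_{gs} = \alpha_g + \beta_s + \varepsilon_{gs}$ by row/column means and
  reports the residual SD per gene, inflated by $\sqrt{g/(g-1)}$ because
  the candidate itself contributes to the sample-effect estimates. With
  group labels, an Andersen-style decomposition is used: for each group
  $k$, the gene's intergroup shift beyond the common shift,
  $d_{gk} = (\bar y_{gk} - \bar y_{g\cdot}) - (\bar y_{\cdot k} - \bar
  y_{\cdot\cdot})$, plus the standard error of its intragroup residual
  variation, averaged over groups:
  $\rho_g = \tfrac1K \sum_k \left(|d_{gk}| + \sqrt{\hat\sigma^2_{gk} /
  n_k}\right)$. This estimator is the package's own (the original
  publication's variance-shrinkage of $d$ is not applied); it is validated
  against an explicit residual oracle and by planted-group-difference
  recovery, not against any web tool's internals. The exact small-sample
  constant is configurable (`inflation = "none"`).
* **geNorm.** Pairwise variation $V_{gh} = \mathrm{SD}_s\,
  \log_2(Q_{gs}/Q_{hs})$ and $M_g = \mathrm{mean}_{h \ne g} V_{gh}$; the
  gene with the highest $M$ is removed and $M$ recomputed until two genes
  remain. Reported $M$ values are from each gene's last round of
  inclusion; the surviving pair — indistinguishable by construction — is
  tied at rank 1.5 by default (`tie_mode = "split"` assigns 1 and 2 by
  final $M$). An elimination tie at the maximal $M$ removes the
  lexicographically last gene id, making runs deterministic. At a common
  amplification factor of 2, first-round $M$ values coincide exactly with
  the delta-Ct values — an algebraic identity the test suite verifies
  numerically to $10^{-10}$ — so the methods diverge only through
  geNorm's iterative exclusion. `genorm_pairwise_variation()` computes
  the classical $V(k/k{+}1)$ guide to how many references to use; the
  package computes it and leaves the judgement to the analyst.

**Comprehensive rank.** The geometric mean of the four method ranks,
ordered ascending; ties break by delta-Ct value, then gene id (no
published convention exists, so the tie-break is simply fixed and
documented). All four methods are invariant under gene-wise constant Cq
shifts; delta-Ct, geNorm and ungrouped NormFinder are additionally
invariant under per-sample shifts.

## Normalization

The normalization factor of a reference set $R$ in sample $s$ is the
geometric mean $F_s = (\prod_{r \in R} Q_{rs})^{1/|R|}$, computed in the
log domain; a target's normalized series is $Q_{ts} / F_s$. Values are
reported in relative units without rescaling to any calibrator sample —
the package documents its own unit convention rather than asserting
anyone else's — and a `calibrator` argument divides the series by its
value in a named sample when a fold-over-baseline reading is wanted.
Failed reactions propagate as missing factors. A scheme listing the same
gene twice collapses to the single-gene scheme, and reference order never
matters.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
tested; its defaults are fixed and are not tuning knobs.

**Counts.** `simulate_counts()` draws negative-binomial counts with
$\mu_{gl} = \frac{\mathrm{libsize}_l}{10^6}\, \mathrm{baseline}_g\,
2^{\,\mathrm{bias}_g\,\mathrm{endocarp}_l}$ over the canonical 20-library
design (`plum_library_design()`: 2 normal cultivars + 2 'Stoneless'
trees × 4 ovary/whole-fruit timepoints + 1 endocarp library each; the
endocarp libraries sit at positions 5/10/15/20 and `L20` is the cascade's
reference). Three planted classes:

* *stable* — no bias, dispersion 0.002, baselines 50–400: per-library CVs
  of ≈ 5–8 %, i.e. genes that genuinely satisfy the strict 11 % dispersion
  screen the cascade ends with (the screen retains only a couple of dozen
  genes out of tens of thousands in real data, so the planted positives
  must be at least this tight);
* *tissue-biased* — dispersion 0.02 and an endocarp bias of 1–3 log2
  units of either sign, emulating the endocarp-divergent behavior that
  disqualifies classical references in this system;
* *noisy* — dispersion 0.3 (CV ≈ 55 %, bracketing the 17–51 % CV range
  observed for the classical reference panel), baselines log-uniform over
  10–500 so that the expression window also has work to do.

Library sizes are uniform over 5–20 million reads. The gamma-Poisson
count model is the standard choice for bulk RNA-seq; in the
dispersion → 0 limit the per-gene CV approaches the Poisson expectation
$1/\sqrt{\mu}$, which the test suite checks by moments.

**Cq data.** `simulate_cq()` builds
$\mathrm{Cq}_{gsr} = b_g + \mathrm{bias}_{gs} + u_s + e_{gs} + \eta_{gsr}$:
a per-gene baseline Cq, optional planted differential-expression offsets,
shared sample effects $u_s \sim N(0, 0.8^2)$ cycles mimicking RNA input
variation (exactly the nuisance reference-gene normalization removes —
making the benefit of normalization demonstrable), per-gene biological
noise of SD $\sigma_g$ (the ground-truth stability parameter), and
replicate noise (SD 0.15 cycles) over triplicates. With probability 0.02
one replicate of a reaction is displaced by 1.5 cycles, large enough to
trigger the 0.5-cycle discard rule. Dilution series come from the same
per-gene curves ($\mathrm{slope} = -1/\log_{10} E$), noiseless by
default so that curve fitting recovers the truth exactly. The default
sample panel is a seven-stage developmental series plus four endocarp
samples (11 samples), mirroring a realistic validation experiment.

**What the generator does not emulate:** mapping bias, rRNA/organellar
contamination, batch effects, primer-specific amplification artifacts,
or gene-gene correlation beyond the shared sample effects. Passing tests
therefore demonstrate correctness of the algorithms and recoverability
under the stated noise model, not performance on any particular real
dataset.

`make_fixture_suite()` pins one canonical dataset (seed 42, byte-stable
across runs): a 120-gene count matrix, and a 14-gene × 11-sample qPCR
experiment — nine tight candidates `P1`–`P9`, one drifting `UBQ`-like
gene, four targets `PT1`–`PT4` with planted endocarp/stage profiles —
plus fivefold dilution series and a normalization-schemes file.

## Numerical choices and degenerate inputs

* Sample SD (n−1 denominator) throughout; the population form is
  available in `summarize_gene()` since integer-rounded published CV
  tables are consistent with either.
* High/low ratios with a zero minimum are reported as undefined (`NA`,
  flagged) rather than infinite; report formatting prints `-`.
* Report rounding (2 d.p. ratios, integer CV) is presentation-only; full
  precision is retained internally.
* Geometric means are computed as `exp(mean(log(x)))`; non-positive
  inputs are hard errors naming the offending gene and sample.
* Fold changes with both group means zero are `NA`; with one zero,
  infinite — either way the gene fails the fold-change window.
* Curve fitting refuses < 3 points and zero-variance abscissae;
  efficiency refuses non-negative slopes.
* Cq matrices must be complete for ranking; the documented practice for
  a failed reaction is to drop that sample's column first.

## Problem sizes used by the test and acceptance suites

Chosen as the package's own testing design: cascade cross-validation on
500 simulated genes plus 50 random threshold settings; class-recovery
rates over 100 simulation seeds of 60 genes; geNorm/delta-Ct equivalence
on 100 random 5 × 8 matrices; full elimination oracles on 4–6 gene
instances; stability parameter recovery over 200 replicates of a
6-gene × 11-sample experiment with planted noise SDs of 0.1 vs 1.0
cycles. These sizes make every property sharply decidable while keeping
the default suite fast.

## Known limitations

* The cascade reproduces the *procedure* of RNA-seq candidate screening;
  published survivor counts from any specific study depend on that
  study's unreleased count data and are not reproducible from summaries.
* Grouped NormFinder omits the original's shrinkage of the intergroup
  difference; with many groups of few samples its values will be
  slightly conservative (larger) relative to the original estimator.
* The comprehensive rank treats the four methods as exchangeable; no
  weighting is offered, matching common RefFinder-style practice.
* No multi-sample count normalization beyond per-library scaling (no
  TMM/median-of-ratios factors) — candidate screening operates on
  whatever normalized layer is supplied.
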