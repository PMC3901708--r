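---
title: "medipDMR: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{medipDMR: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical models the package implements,
the tunable parameters and their defaults, what the synthetic-cohort
generator does and does not emulate, and the numerical and design
choices made where more than one reasonable option existed. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## 1. The measurement and its preprocessing

A two-colour MeDIP-chip experiment measures, per probe and array, a
bound (immunoprecipitated, methylation-enriched) and an input channel.
The analysis quantity is the normalized `log2(bound/input)` ratio.

**Background subtraction.** When the scanner provides background
columns they are subtracted per channel; otherwise the per-array,
per-channel 1st-percentile intensity is used as a robust offset. Both
channels are floored at `eps = 1` intensity unit so the ratio stays
finite; negative raw intensities are retained up to that point (they are
flagged in QC, not clipped at parse time).

**Quantile normalization.** Each array's sorted ratios are replaced by
the across-array mean of order statistics, preserving ranks; tied values
receive the mean of the quantile values their (fractional average) ranks
span. This rule is deterministic and idempotent, and after it all arrays
share one value multiset exactly. Normalization is performed across all
arrays jointly (cases, controls and replicates together); a
within-replicate-pair variant would protect against group-scale
artefacts but discards the cross-array exchangeability the promoter test
assumes, and is not the default.

**QC.** Per array: median M (`log2` ratio), median A, M-vs-A slope,
fractions of negative/saturated probes, and the correlation between
replicate arrays of one subject (reported absent — never zero — for
single-replicate subjects). Flags (default `|median M| > 1` or replicate
correlation < 0.8) warn rather than exclude: visual QC practice for
these arrays is advisory, and exclusion is the caller's decision via the
`exclude` argument of `mergeReplicates()`.

**Replicate merge.** Per-subject probe values are the unweighted mean of
the subject's replicate arrays — symmetric, permutation-invariant, and
the natural choice when replicates are exchangeable hybridizations of
one sample.

## 2. Two-level differential methylation calling

**Probe level.** For each probe the group difference of merged ratios
(`log2FC`) is tested with a moderated t-statistic. The per-probe pooled
variance `s_g^2` (df `d_g = n1 + n2 - 2`) is shrunk toward a prior
variance `s0^2` with prior df `d0`, both estimated by method of moments
on `z = log s_g^2` under the scaled-F sampling model: with
`e = z - digamma(d_g/2) + log(d_g/2)`, solve
`trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))` by Newton inversion of
the trigamma function, and recover `s0^2` from `mean(e)` with the
digamma correction. When the spread of `z` does not exceed what sampling
variation alone explains, `d0 = Inf` and every probe is tested as a
z-statistic against `s0^2 = mean(s_g^2)`. The two limits are exact:
`d0 = 0` reproduces the classical pooled t, `d0 = Inf` the z-statistic
(both asserted numerically in the tests, and the whole route is
cross-checked against an independent implementation of the same
empirical-Bayes model).

**Promoter level.** Promoters with at least `min_probes = 3` scored
probes (fewer make a rank test uninformative) are tested by the Wilcoxon
rank-sum statistic of their probes' t-values against **all probes
outside the promoter** — the comparison population matching the idea of
promoters "enriched" for extreme probe statistics. One-sided p-values in
both directions come from the normal approximation with tie correction
and a 0.5 continuity correction; when the promoter has at most 8 probes
and the array at most 25 in total, exhaustive enumeration over all
`C(N, k)` probe subsets is used instead. The reported two-sided p is
`min(1, 2 min(p+, p-))`, the direction is the smaller side, and q-values
are Benjamini–Hochberg over tested promoters (the field-default step-up
procedure, used because the promoter-level FDR method is otherwise a
free choice).

**Call rule.** A promoter is called iff `q <= 0.05` and at least one of
its probes has uncorrected `p <= 0.05`, `|log2FC| >= 0.25`, and a fold
change whose sign matches the promoter direction. Probe p-values are
deliberately not multiplicity-corrected — they act only as a
biological-relevance gate inside the call rule, never as stand-alone
findings. The sign-consistency requirement is this package's addition
(a probe significant in the opposite direction should not qualify a
call); it can be disabled with `sign_consistent = FALSE`.

**Heatmap selection and clustering.** One probe per called gene, the one
with the most extreme `|t|` (ties broken by the smaller genomic start
coordinate, making the selection order-invariant); rows and columns are
clustered with Ward's minimum-variance linkage (`ward.D2`) on
`1 - Pearson r` distance.

## 3. Deconvolution of absolute methylation

MeDIP enrichment is relative; to sanity-check that it tracks absolute
methylation the package implements a transparent grid-posterior
deconvolution rather than a full dinucleotide-resolution coupling model:
per promoter, cohort-averaged probe ratios are modelled as
`r_j ~ Normal(a m w_j + b, sigma^2)` with coupling weight `w_j` = the
probe's fragment-scale CpG count normalized to the promoter maximum, a
uniform prior for `m` on a `[0, 1]` grid (step 0.01), and a posterior
mean/SD per promoter. The gain and offset are estimated globally by
regressing the array-wide mean ratio on the coupling weight binned by
CpG count, with the slope converted to a gain through a prior mean
methylation `m_ref = 0.5`; `sigma` defaults to that regression's
residual SD (floored at 1e-3). Promoters with no CpG-bearing probe are
excluded with an explicit reason. The estimate is monotone in the
promoter's ratios and exact to the grid when `(a, b)` are known and the
noise vanishes. Absolute calibration of `m_hat` depends on `m_ref`; its
*ranking* does not, which is why the accompanying check
(`methylationExpressionAssociation()`: twenty 5%-wide expression
percentile bins plus a global Spearman correlation) uses rank
statistics.

## 4. Genomic organization statistics

**Normalized CpG density.** Per region,
`rho = [cpg/(L-1)] / [(c/L)(g/L)]` — observed CpG dinucleotide density
over the density expected from the C and G mononucleotide frequencies.
`N` bases are excluded from counts and from the effective length.
Hyper- vs hypomethylated call groups are compared with a two-sided
Mann–Whitney U test (no normality assumption for ratio statistics).

**Spatial correlation curve.** For each genomic distance bin,
same-chromosome probe pairs separated by a distance in the bin are
collected (uniformly subsampled without replacement down to
`pair_cap = 200,000` pairs when there are more; the cap and seed are
recorded), and the Pearson correlation of the two probes'
between-group differences is computed with both pair orientations
included. Uncertainty: a 2.5–97.5% bootstrap interval from 1,000
resamplings of pairs with replacement; the null: 500 random permutations
of probe coordinates within each chromosome (equivalently, permutations
of the difference values over fixed coordinates — the implementation
uses this equivalence so pair sets are reused), pooling all permuted
correlations per bin and taking the central 95%. The **decorrelation
length** is the upper edge of the largest-distance bin such that every
bin at or below it has its bootstrap interval disjoint from the null
band (0 if none).

**Distance bins.** The package default is 0, 50 kb, then log-spaced to
4 Mb (14 bins), a resolution suited to full-scale arrays. At the
package's desk scale (2,000 promoters on one chromosome) most of those
bins contain too few *independent* promoter pairs for stable estimates
— probe pairs within a promoter pair are strongly correlated, so the
effective sample size is the promoter-pair count. The recovery analyses
therefore use five coarse bins with edges at 50 kb, L/3, L, 2L and 4L
for the simulated 1.5 Mb cluster scale L, aligning each bin with the
question it answers (short-range structure; persistence to L; decay by
2L; absence beyond).

## 5. The pooled beta-value arm

Bisulfite-array validation uses pooled samples (three pools per group).
CpGs are dropped when any pool's detection p exceeds 0.001 — stricter
than removing single beta values, but with n = 3 pools a missing value
cripples the test — or when a SNP lies within 10 bp of the CpG
(inclusive boundary, the conservative reading). The differential test is
a Welch t on M-values `log2(beta/(1-beta))` with betas clipped to
[0.01, 0.99] before the logit (avoiding infinities; configurable),
plus BH FDR; this transparent combination stands in for proprietary
bead-array software output and is cross-checked against `t.test()`.
Significant CpGs map to promoters through the array design's strand-aware
TSS −1000..+200 windows, keeping both arms of the analysis on one
promoter definition.

## 6. The synthetic-cohort generator

`simConfig()` defaults encode the study conditions the pipeline targets:
5 case vs 14 control subjects, two replicate arrays each, 2,000 genes
(one promoter per gene at desk scale; full scale is a configuration
change), 100 bp probe spacing across TSS −1000..+200, a 2% promoter
effect fraction with an 82% hypomethylated-in-case direction bias,
effect size 0.3 on the methylation scale, 1.5 Mb effect clustering, and
three pools per group for the beta arm.

**Geometry and sequence.** Promoters are laid on one synthetic
chromosome at uniform 30–150 kb spacing. Each promoter gets a CpG-density
class (low/mid/high, 40/40/20%) and a window sequence: CpG-depleted
random background (80% of background CG dinucleotides mutated, matching
the strong CpG depletion of vertebrate genomes) plus a Poisson number of
injected CpGs per class (6/15/45 per 1,200 bp window). Probe CpG counts
are computed from these sequences, so the count invariants hold by
construction.

**Effects.** Cluster centres are drawn among promoter positions; effect
probability decays exponentially with distance to the nearest centre at
scale `cluster_scale` and is *truncated at one scale length*. The
truncation is deliberate: with an unbounded exponential halo the
spatial correlation of group differences provably stays above the
permutation null band far beyond twice the scale, so a finite
decorrelation length would not exist to recover. With clusters of
radius L, within-cluster pair separations cannot exceed 2L, making
"decay by twice the cluster scale" a structural property. The
proportionality constant is solved so the expected effect count equals
`effect_fraction * n_genes` even where probabilities saturate at 1.
Directions are independent Bernoulli draws at the configured bias (so
the hypomethylated fraction is binomial around 0.82); density classes
are then reassigned for effect promoters, tilted toward high density
for hypermethylated and low density for hypomethylated effects — the
observed/expected density asymmetry seen in this kind of data, in both
directions.

**Measurement model.** For probe j of promoter i and subject s the true
ratio is `r = gain * m[i,s] * w_j + offset` with `w_j` the probe's
CpG count within ±300 bp (MeDIP enrichment integrates methylation over
the immunoprecipitated fragment, so coupling extends well beyond the
50 bp probe; with probe-window counts alone, most probes of a true
effect promoter would carry no signal, which is not how MeDIP-chip
behaves) normalized to the promoter maximum. Noise: a fixed per-probe
affinity effect (SD 0.25), a per-array shift (SD 0.1), subject-by-probe
biological noise shared by a subject's replicates (SD 0.10), and
array-by-probe replicate noise (SD 0.12), all Gaussian on the log2
scale; the input channel is log-normal and `bound = input * 2^r`.
Baseline methylation is drawn in [0.25, 0.75] so ±0.3 effects are fully
expressed without clipping. No published noise magnitudes exist for
these arrays; the SDs were calibrated once so that the analysis at the
study's sample sizes has substantial but not trivial power and the
spatial statistics are estimable at desk scale, and are configuration
parameters, not constants. Probe-level noise is independent across
probes — exactly the exchangeability the promoter rank-sum test
assumes, which is what makes the null-calibration suite a meaningful
test of the test rather than of a violated assumption.

**What passing tests do and do not show.** The generator emulates the
statistical structure the pipeline assumes: it does not model probe
sequence thermodynamics, dye swaps, batch or plate effects, copy-number
variation, cell-composition differences, or correlated biological
variation between neighbouring probes under the null. Calibration and
recovery results on these cohorts therefore demonstrate correctness of
the implementation under its stated assumptions, not robustness of the
method to real-array artefacts.

## 7. Problem sizes and seeds

The calibration/recovery suites and the acceptance script run the full
pipeline at the study's subject-level design (5 vs 14, two replicates)
on 2,000-gene cohorts, three seeds for calibration and recovery; the
spatial curve uses the full 1,000 bootstraps and 500 permutations with
the 200,000 pair cap. Unit tests use miniature designs (toy promoters,
25-probe arrays) where exhaustive enumeration is feasible. Every
stochastic step takes an explicit seed and restores the caller's RNG
state, so all reported numbers are bit-reproducible.

## 8. Known limitations

- One promoter per gene at desk scale; multi-TSS genes share probes by
  the overlap rule but are not exercised by the default generator.
- The deconvolution is a sanity-check model: linear CpG coupling, global
  gain/offset, no per-sample posterior.
- The decorrelation length is bin-edge-quantized; its resolution is the
  bin grid.
- The 450K arm models pool composition only through group means;
  within-pool subject variance is not separately identifiable with three
  pools and is folded into the beta noise SD.
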