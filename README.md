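# medipDMR

Differential promoter methylation calling for two-colour MeDIP promoter
tiling arrays, with the downstream statistics such studies report:
genome-organization of the differences, absolute-methylation estimates,
a pooled bisulfite-array (450K-style) validation arm, and
signature-overlap tests.

## What it is for

MeDIP-chip experiments immunoprecipitate methylated DNA fragments with an
anti-5-methylcytosine antibody and hybridize bound and input fractions to
a promoter tiling array (probes at 100 bp spacing across TSS −1000..+200
windows). Given per-array bound/input intensities, a sample sheet and the
array design, `medipDMR` identifies promoters differentially methylated
between two groups of subjects (here labelled CPA vs NPA, case vs
control), at case/control sample sizes as small as 5 vs 14 with two
replicate arrays per subject.

The calling procedure is two-level:

1. **Probe level** — an empirical-Bayes moderated t-statistic per probe.
   The pooled within-group variance `s_g²` (df `d_g`) is shrunk toward a
   prior fitted by method of moments on `log s_g²` under the scaled-F
   model `s_g² ~ s₀² F(d_g, d₀)`:

   ```
   s̃² = (d₀ s₀² + d_g s_g²) / (d₀ + d_g)
   t̃  = (mean_case − mean_control) / (s̃ √(1/n₁ + 1/n₂))
   ```

   with p-values from the t distribution on `d₀ + d_g` df.

2. **Promoter level** — a Wilcoxon rank-sum test of the promoter's probe
   t̃ values against all probes outside the promoter, one-sided in both
   directions (normal approximation with tie and continuity correction;
   exhaustive enumeration for small cases), combined as
   `p = min(1, 2·min(p⁺, p⁻))`, with Benjamini–Hochberg FDR across
   promoters.

A promoter is called differentially methylated when its FDR is ≤ 0.05
**and** it contains at least one probe with uncorrected p ≤ 0.05 and
|log2 fold change| ≥ 0.25 whose sign matches the promoter direction.

Around that core the package provides: quantile normalization of
log2(bound/input) ratios with QC summaries and replicate merging;
heatmap probe selection (most extreme t̃ per gene) with Ward/Pearson
clustering; a grid-posterior deconvolution of absolute promoter
methylation from CpG-coupled enrichment; observed/expected CpG density
statistics; distance-binned spatial correlation of between-group
differences with bootstrap CIs against a coordinate-permutation null
(and the derived decorrelation length); pooled beta-value differential
analysis with detection-p and SNP-proximity filters; and hypergeometric /
Fisher-exact overlap machinery for comparing signatures across cohorts
and platforms.

A first-class synthetic-cohort generator (`simConfig()`,
`simulateTruth()`, `simulateMedipArrays()`, `simulate450kPools()`)
produces ground-truthed cohorts with the statistical structure the
analysis assumes — spatially clustered effects with a hypomethylation
direction bias, direction-linked CpG density, replicate arrays, pooled
beta tables — so the whole pipeline is testable end to end without any
external data.

## Worked example

```r
library(medipDMR)

# a small synthetic cohort: 300 genes, 5 case vs 14 control subjects,
# 2 replicate arrays each, 2% of promoters carrying effects
cohort <- simulateCohort(simConfig(n_genes = 300), seed = 7)
design <- truthDesign(cohort$truth)

ratios  <- normalizeRatios(cohort$arrays, cohort$arrays$samples)
merged  <- mergeReplicates(ratios)
ps      <- probeModeratedT(merged)
prs     <- promoterRankSum(ps, design)
dmr     <- callDmrs(ps, prs, design)
dmr$direction_counts
#> hyper  hypo
#>     0     4

est <- estimatePromoterMethylation(merged, design)
cor(est$m_hat, truthTable(cohort$truth)$m0, method = "spearman",
    use = "complete.obs")
#> [1] 0.9192
```

Four promoters are called at FDR ≤ 0.05, all hypomethylated in the case
group, consistent with the simulated direction bias; the deconvolved
absolute methylation estimates rank-correlate at ρ ≈ 0.92 with the
simulated truth. `runDemo(out_dir)` performs the same analysis through
the file-based pipeline (`runPipeline()`), writing per-stage TSV/BED
outputs and a reproducibility manifest.

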