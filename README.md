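# nedomains

Genome-wide analysis of nuclear-envelope (NE) association from DamID
tiling-microarray data, as a tidyverse-native R package. DamID tethers
*E. coli* Dam methyltransferase to a nuclear-envelope protein — a lamin
(LMN-1-like) or an inner-membrane factor (emerin/EMR-1-like) — and reads
out contact as a per-probe log2 ratio against a freely diffusing Dam
control. `nedomains` turns those probe-level log-ratios into:

- **normalized score tracks** — GC-stratified robust standardization per
  replicate, 300-bp median smoothing, quantile normalization jointly over
  all replicates and backgrounds, and replicate averaging;
- **NE-associated domains** (LADs/EADs) — probe scores are binarized to
  ±1, averaged in 200-probe windows sliding one probe at a time, and
  windows with mean ≥ θ (default 0.8) are merged into domains. θ is
  calibrated so the empirical false discovery rate against a
  control-vs-control null track stays below 5%:
  `FDR(θ) = P(null window ≥ θ) / P(signal window ≥ θ)`;
- **factor-exclusive elements** — regions with ≥ 10 probes scoring ≥ 1 on
  one factor and < 0 on the other, each qualifying probe ≤ 500 bp from
  the next — and **detached regions**, the same chaining applied to a
  wild-type minus mutant difference track;
- **annotation statistics** — domain-boundary metaprofiles, gene-body
  occupancy, strand-aware promoter/exon/intron enrichment by one-sided
  exact binomial tests, Wilcoxon rank-sum gene-set comparisons, and track
  correlations;
- **transcriptional de-repression** — exon-median expression, quantile
  normalization, per-locus medians, and a SAM-style permutation statistic
  `d = (mean_mut − mean_wt) / (s + s0)` with significance at Δ > 4 on the
  deviation from permutation-expected order statistics.

A first-class synthetic-data module (`make_genome()`,
`plant_architecture()`, `simulate_damid()`, `make_genes()`,
`simulate_expression()`) generates seeded probe layouts, arm-enriched
domain architectures with planted exclusive elements and detached
regions, AR(1)+GC-biased replicate tracks, a null control, and
overdispersed expression counts — so every stage is testable against
known ground truth without downloading array data.

The package is aimed at chromatin/regulatory genomics analysts who want
the published window-FDR domain-calling procedure as inspectable,
composable functions rather than a fixed script.

## Worked example

Simulate a three-chromosome study, normalize it, calibrate the window
threshold against the null control, and call domains:

```r
library(nedomains)

layout <- make_genome(c(chrI = 6e6, chrII = 5e6, chrX = 4e6), seed = 1)
arch   <- plant_architecture(layout, seed = 2)
noise  <- noise_model(sd = 0.5, ar1 = 0.5, gc_slope = 0.02, n_reps = 3, seed = 3)
sim    <- simulate_damid(layout, arch, noise, factor = "A")

tracks <- ma2c_normalize(list(A = sim$signal, null = sim$null))

params  <- domain_params()                       # 200 probes, theta 0.8, FDR < 5%
ws      <- window_scores(binarize(tracks$A), params)
ws_null <- window_scores(binarize(tracks$null), params)
glance(calibrate_fdr(ws, ws_null, params))
#>   selected_theta default_theta default_theta_fdr default_theta_ok ceiling
#> 1            0.5           0.8                 0 TRUE                0.05

doms <- call_domains(ws, params, theta = 0.8, label = "LAD")
doms
#>   chrom start    end label n_probes n_windows score
#> 1 chrI  11800  24700 LAD        258        59 0.921
#> 2 chrI  34900  55750 LAD        417       218 0.981
#> 3 chrI  61150 106750 LAD        912       713 0.994
#> # 246 more rows

gaps_and_stats(doms, layout)$summary[c("n_domains", "coverage",
                                       "domain_median", "gap_median")]
#>   n_domains coverage domain_median gap_median
#> 1       249    0.415         20500      11475

truth <- subset(arch$domains, factor == "A")
interval_jaccard(doms[c("chrom", "start", "end")],
                 truth[c("chrom", "start", "end")])
#> [1] 0.914
```

Reading the output: the conventional window threshold of 0.8 keeps the
empirical FDR at 0 (well under the 5% ceiling), and 249 called domains
cover 41.5% of the synthetic genome with a median size of about 20 kb —
a base-pair Jaccard of 0.91 against the planted truth. `run_pipeline()`
chains all stages (normalization → domains → elements → annotation →
expression) from a single seeded config and writes bedGraph/BED/TSV
outputs plus a checksummed manifest; `autoplot()` methods cover the FDR
calibration, SAM fit and chromosome-occupancy regression, and `tidy()` /
`glance()` give broom-style summaries of every fitted object.

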