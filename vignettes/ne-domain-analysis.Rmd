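---
title: "Calling nuclear-envelope-associated domains: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling nuclear-envelope-associated domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nedomains)
```

# The problem

DamID profiles genome–nuclear-envelope contact by fusing *E. coli* Dam
methyltransferase to an envelope protein: adenines near contact sites are
methylated, and a tiling microarray reads out, per ~50-bp probe, the log2
ratio of the fusion signal over a freely diffusing Dam control. Two
factors are profiled — a lamin-like tether (factor A in the synthetic
module) and an emerin-like inner-membrane protein (factor B) — in
replicate, together with a control-vs-control self-comparison track that
carries no real signal and serves as the empirical null.

This vignette documents the models each stage implements, the parameters
that matter, what the synthetic generator does and does not emulate, and
the design decisions taken where the published procedure leaves room.

# Normalization: from raw log-ratios to scores

`ma2c_normalize()` applies, in order:

1. **GC-stratified robust standardization** (`gc_normalize()`). Probes
   are binned by integer GC count (bin width 1 by default; bins with
   fewer than 50 probes merge into the nearest neighbour). Within a bin,
   `score' = (score − median) / (1.4826 × MAD)`, where MAD is the raw
   median absolute deviation; 1.4826 makes the scale consistent with the
   standard deviation under Gaussian noise. A zero MAD (constant bin)
   falls back to scale 1 with a warning. Any probe effect that is a
   function of GC content — in particular a linear GC bias — is removed;
   on simulated null tracks the residual score–GC correlation is below
   0.05 (tested).
2. **300-bp median smoothing** (`median_smooth()`). Each probe takes the
   median of all probes whose start lies within ±150 bp of its own,
   itself included; chromosome ends use the truncated window. On a
   uniformly spaced layout this is a running median of fixed odd width
   and is computed by `stats::runmed` with the ends handled exactly.
3. **Quantile normalization** (`quantile_normalize()`, via
   `limma::normalizeQuantiles` with tie averaging) applied **jointly**
   over every replicate of every strain *and* the null background, so
   all intensity distributions are directly comparable.
4. **Replicate averaging** (`average_replicates()`), with the pairwise
   Pearson correlation matrix attached and logged.

*Score-scale caveat.* Standardizing by the MAD of the probe population —
a mixture of in-domain and out-of-domain probes — and then quantile
normalizing together with a signal-free null compresses the score scale:
a latent level planted at 1.5 raw score units realizes at roughly 1.0
after the full chain. Domain calling is sign-based and unaffected, but
the exclusive-element rule thresholds absolute scores (≥ 1). The
recovery analyses for elements and detached regions therefore run the
caller on median-smoothed, replicate-averaged tracks with no GC bias
planted (and hence none to remove), so the planted levels are expressed
on the same scale the thresholds refer to. For the same reason the
end-to-end pipeline's default architecture plants exclusive elements at
an own-factor level of 2.0: elements are by definition regions of strong
own-factor signal.

# Domain calling and FDR calibration

Scores are binarized to ±1 (`binarize()`; an exact 0 maps to −1, the
conservative choice, so ambiguous probes never extend a domain). Windows
of 200 probes (~10 kb at 50-bp spacing) slide one probe at a time, never
crossing a chromosome boundary, and each window's value is the mean of
its signs (`window_scores()`). Windows with value ≥ θ become genomic
spans — first probe start to last probe end — and any spans sharing at
least 1 bp are merged into domains (`call_domains()`); abutting spans
stay separate. Raising θ can only shrink the result (tested property).

θ is calibrated against the self-comparison null (`calibrate_fdr()`):
`FDR(θ)` is the fraction of null windows at or above θ divided by the
fraction of signal windows at or above θ, capped at 1. The function
reports both the smallest grid value whose FDR is below the 5% ceiling
and whether the conventional θ = 0.8 passes; the pipeline uses 0.8
whenever it passes, mirroring the published choice of a fixed threshold
validated by the null. On an i.i.d. ±1 null the exact binomial tail
P(window ≥ 0.8) ≈ 10⁻³³, so any observed null exceedance comes from
autocorrelation — which is exactly why the synthetic noise is AR(1) and
why the calibration is non-trivial.

Edge behaviour worth knowing: the window-to-domain conversion
systematically over-calls each boundary by the fraction of a window the
threshold tolerates (~1–2 kb per side at θ = 0.8), and no domain
shorter than one window span can be called at all. These are properties
of the published method, not of this implementation; they bound the
achievable recovery Jaccard at roughly 0.91–0.93 under the default
architecture.

# Exclusive elements and detached regions

`call_exclusive_elements()` takes the two factors' averaged tracks over
one probe grid. A probe qualifies when its own-factor score is ≥ 1 and
the other factor's score is < 0 (strict). Qualifying probes chain while
consecutive **start-to-start** distances stay ≤ 500 bp — start-to-start
because overlapping probes make end-to-start gaps ill-defined — and
non-qualifying probes inside a chain never break it; only spacing does.
Chains of ≥ 10 qualifying probes are emitted as elements spanning the
first qualifying start to the last qualifying end.

`call_detached_regions()` reuses the same chaining on the wild-type
minus mutant difference track, with the own-score minimum acting as the
detachment threshold and no second-track condition. The published work
reports detached regions without stating their rule; reusing the
element rule keeps a single documented convention, and the threshold,
probe count and gap are all exposed in `element_params()`.

# Annotation statistics

- `boundary_metaprofile()` averages any probe-level secondary signal in
  fixed offset bins around domain left edges (optionally both edges,
  with the right edge mirrored so positive offsets point into the
  domain).
- `gene_occupancy()` averages probe scores over the span between
  transcription start and end sites, strand-independent; genes with a
  positive mean are classed "anchored".
- `feature_enrichment()` classifies every probe with the fixed
  precedence promoter > exon > intron (promoters are strand-aware, 3 kb
  upstream of the TSS), takes the probe universe's class fractions as
  background, and computes one-sided exact binomial tails — upper tail
  when the observed fraction exceeds background, lower otherwise. The
  probe, not the base pair, is the unit, because the tested objects are
  probe sets.
- `compare_gene_sets()` is a Wilcoxon rank-sum test; small samples get
  an exact p by full enumeration of group assignments (valid under
  ties), untied small samples the exact Wilcoxon distribution, and
  larger samples the tie-corrected normal approximation.
- `track_correlation()` is Pearson correlation over paired probes,
  optionally after 100-kb bin averaging.

# Expression and SAM-style selection

Exon expression is the median per-base coverage over the exon's range;
locus expression is the median over the locus's distinct exons — both
order-invariant and robust to a single outlying exon.
`expression_matrix()` quantile-normalizes the exon-by-sample table
across samples before collapsing to loci.

`sam_select()` computes, per locus, `d = (mean_b − mean_a) / (s + s0)`
with `s` the pooled standard error. Expected order statistics come from
label permutations: all `choose(n, n_b)` assignments are enumerated when
that count is within budget (with 3 + 2 samples there are only 10, and
balanced permutations do not exist for unequal groups), otherwise a
seeded sample is drawn. A locus is significant when its sorted d
deviates from the permutation-expected value by more than Δ (default 4),
using the standard cut-point rule: everything beyond the first
exceedance on each side.

**Fudge-factor rule.** The default sets `s0` to the median of the
per-locus standard errors (the `s0.perc = 50` convention of samr). The
classic alternative — scanning the percentiles of `s` for the one
minimizing the coefficient of variation of the d spread across
s-quantile windows — is available as `s0_rule = "cv"`, but it presumes
the spread of the mean differences scales with `s`. On overdispersed
count medians `s` spans orders of magnitude while the differences do
not, the CV objective then decreases monotonically in `s0`, and the rule
runs to the top percentile, deflating every d below any useful Δ. The
median rule is stable in both regimes, which is why it is the default.

**Quantile normalization and fold changes.** With 2 of 5 samples
carrying a 4-fold tail in ~5% of loci, joint quantile normalization maps
the tail to the average of the per-sample top order statistics and
compresses the realized fold change to roughly 2×. The d statistic
still separates planted loci cleanly because their within-group spread
shrinks in step; the recovery analyses report recall ≥ 0.9 with ≤ 2
false positives under the conditions below, and 20 pure-null
simulations yield a median of 0 significant loci at Δ = 4.

# The synthetic generator: what it emulates, and what it does not

`make_genome()` lays 50-bp probes at 50-bp spacing (both configurable)
and draws integer GC counts (binomial with per-base GC 0.36 by default,
or uniform, or any user function). `plant_architecture()` fills
chromosome arms (outer 30% per side by default; the fixed arm table of
the *C. elegans* chromosomes ships as `celegans_arms()`) to a target
domain density of 0.6 and centers to 0.05, exact by construction.

Parameter choices, made once:

- **Domain sizes**: lognormal, median 23 kb, `sdlog` 0.6, truncated to
  [10.5 kb, 300 kb] — matching the observed size range and medians of
  adult NE-associated domains, with the lower bound just above one
  200-probe window span because a sub-window domain is invisible to the
  caller by construction and would make ground truth unrecoverable in
  principle rather than in practice.
- **Gaps**: lognormal, median 15 kb, minimum 5 kb (observed gap medians
  are 13.5–19.2 kb; the floor keeps adjacent boundary over-calls from
  bridging).
- **Exclusive elements**: 600–3000 bp (observed range 339–3328 bp,
  median 763 bp), planted inside shared domains with a one-domain-floor
  margin and punched out of the other factor's copy, so element bp never
  overlaps the other factor's domains and the punched flanks remain
  callable domains.
- **Detached regions**: whole element-free domains that factor A
  abandons in the mutant genotype.
- **Noise** (`noise_model()`): stationary AR(1) Gaussian per replicate
  (default sd 0.5, lag-1 correlation 0.5) plus a linear GC bias
  (0.02 score units per mean-centred GC count). The AR(1) structure is
  what makes window-FDR calibration non-trivial — i.i.d. noise never
  produces a positive null window. The source study states no noise
  model; these are artifact choices, all exposed.
- **Expression** (`simulate_expression()`): gamma-Poisson per exon,
  baseline mean coverage 200 (comfortably above the Poisson floor, as
  for well-expressed loci at typical sequencing depth), dispersion 0.05
  for the pipeline showcase and 0.002 for the "strong effect, low
  dispersion" recovery scenario; genes overlapping detached intervals
  get 4× baseline in non-reference groups. Synthetic genes carry 4–8
  exons for typical spans, as in compact metazoan genomes; exon-poor
  genes have noisier locus medians and are the first to suffer from
  quantile-normalization distortion.

Not emulated: raw reads or array images, hybridization chemistry,
dye effects, probe-sequence affinity beyond the linear GC term,
cross-assembly coordinate conversion, and real *C. elegans* sequence
composition. Passing recovery tests therefore demonstrate that the
procedures are implemented correctly and behave as designed under
realistic signal, autocorrelation and bias — not that the thresholds
are optimal for any particular real array platform.

# Numerical and interface conventions

- All coordinates are 0-based half-open, internally and in BED/bedGraph
  output; the 1-based inclusive arm table is converted on load.
- Every generator is a pure function of its seed; `run_pipeline()`
  derives all stage seeds from one master seed and two runs with the
  same config are checksum-identical (tested).
- Binarization maps exact zeros to −1; the FDR at thresholds with no
  signal windows is undefined and excluded from selection; a zero MAD
  bin standardizes with scale 1; a zero reference mean flags a fold
  change undefined rather than dividing by zero.
- Problem sizes in the shipped checks: the domain-recovery analysis uses
  one 15-Mb chromosome (300,000 probes, 3 replicates), element and
  detached recovery use ten 7-Mb two-chromosome studies, and the
  expression analyses use 1,000 loci with 3 + 2 samples — large enough
  that the binomial and CLT-scale tolerances in the tests are sharp,
  small enough to iterate on comfortably.

# Known limitations

- Boundary over-call of up to ~2 kb per side and blindness to
  sub-window domains are inherited from the window procedure itself.
- The detached-region rule is a documented stand-in; the source
  procedure is unpublished.
- Quantile normalization assumes identical intensity distributions
  across samples; with strong asymmetric de-repression it compresses
  fold changes (and slightly distorts the top ranks of unaffected
  samples). Fold changes reported by `fold_change_table()` are on the
  normalized scale.
- The X chromosome is identified by name pattern for the occupancy
  regression; non-standard chromosome names need `autosome_pattern`.
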