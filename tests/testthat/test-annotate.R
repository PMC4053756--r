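test_that("boundary metaprofiles average the secondary signal by offset", {
  doms <- tibble::tibble(chrom = "chrA", start = 5000L, end = 20000L, label = "EAD")

  # constant secondary track: profile identically that constant
  tr <- toy_track(rep(3.5, 400)) # covers 0..20 kb
  prof <- boundary_metaprofile(tr, doms, flank_bp = 2000, step_bp = 500)
  expect_true(all(prof$mean_score[prof$n_probes > 0] == 3.5))

  # flank smaller than step collapses to a single bin
  one <- boundary_metaprofile(tr, doms, flank_bp = 200, step_bp = 1000)
  expect_equal(nrow(one), 1)

  expect_error(
    boundary_metaprofile(tr, doms[0, ], flank_bp = 2000),
    "no domains"
  )
})

test_that("metaprofiles show the planted step and flatten under shuffling", {
  st <- small_study(71, chrom_lengths = c(chrA = 5e6), n_elements = c(A = 0, B = 0), n_detached = 0)
  truth <- st$arch$domains[st$arch$domains$factor == "A", c("chrom", "start", "end")]
  step_track <- st$layout
  step_track$score <- as.numeric(nedomains:::overlaps_any(st$layout, truth))

  prof <- boundary_metaprofile(step_track, dplyr::mutate(truth, label = "LAD"),
    flank_bp = 5000, step_bp = 500
  )
  outer_bins <- prof$mean_score[prof$offset_mid < -2500]
  inner_bins <- prof$mean_score[prof$offset_mid > 2500]
  expect_lt(mean(outer_bins), 0.35)
  expect_gt(mean(inner_bins), 0.9)

  # shuffled boundaries give a flat profile
  shuffled <- truth
  shuffled$start <- withr::with_seed(72, sample.int(4.9e6, nrow(truth)))
  shuffled$end <- shuffled$start + (truth$end - truth$start)
  prof2 <- boundary_metaprofile(step_track, dplyr::mutate(shuffled, label = "x"),
    flank_bp = 5000, step_bp = 1000
  )
  expect_lte(max(prof2$mean_score) - min(prof2$mean_score), 0.15)
})

test_that("gene occupancy averages overlapping probes and flags missing genes", {
  tr <- tibble::tibble(
    chrom = "chrA", start = c(1100L, 1500L, 9000L), end = c(1150L, 1550L, 9050L),
    score = c(1, 3, 7)
  )
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "chrA",
    start = c(1000L, 5000L), end = c(2000L, 6000L),
    strand = c("+", "-"), tissue = "none"
  )
  occ <- gene_occupancy(tr, genes)
  expect_equal(occ$occupancy, c(2, NA))
  expect_equal(occ$n_probes, c(2L, 0L))
  expect_equal(occ$anchored, c(TRUE, NA))

  # strand-independent: flipping strand changes nothing
  flipped <- genes
  flipped$strand <- c("-", "+")
  expect_equal(gene_occupancy(tr, flipped)$occupancy, occ$occupancy)

  # uniform track gives every covered gene the same value
  tru <- toy_track(rep(2.5, 100))
  genes2 <- tibble::tibble(
    gene_id = "g", chrom = "chrA", start = 100L, end = 900L,
    strand = "+", tissue = "none"
  )
  expect_equal(gene_occupancy(tru, genes2)$occupancy, 2.5)
})

test_that("feature enrichment matches exact binomial tail sums", {
  # random configurations against the first-principles oracle
  for (seed in 1:20) {
    cfg <- withr::with_seed(seed, {
      n <- sample(10:500, 1)
      list(n = n, x = sample(0:n, 1), p = runif(1, 0.05, 0.95))
    })
    up <- stats::pbinom(cfg$x - 1, cfg$n, cfg$p, lower.tail = FALSE)
    lo <- stats::pbinom(cfg$x, cfg$n, cfg$p)
    expect_equal(up, oracle_binom_upper(cfg$x, cfg$n, cfg$p), tolerance = 1e-10)
    expect_equal(lo, oracle_binom_lower(cfg$x, cfg$n, cfg$p), tolerance = 1e-10)
  }

  # closed forms: all-out depletion and the 30-of-100 promoter example
  expect_equal(
    stats::pbinom(0, 100, 0.25),
    0.75^100,
    tolerance = 1e-12
  )
  expect_equal(
    stats::pbinom(29, 100, 0.2, lower.tail = FALSE),
    oracle_binom_upper(30, 100, 0.2),
    tolerance = 1e-10
  )
})

test_that("feature enrichment classifies probes with promoter precedence", {
  # one + strand gene: span 10000-16000, exon 10000-12000, promoter 7000-10000
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chrA", start = 10000L, end = 16000L,
    strand = "+", tissue = "none",
    exons = list(tibble::tibble(start = 10000L, end = 12000L))
  )
  n <- 400
  tr <- toy_track(rep(0, n)) # 0..20 kb
  elements <- tibble::tibble(chrom = "chrA", start = 7000L, end = 9000L)
  enr <- feature_enrichment(tr, elements, genes, promoter_bp = 3000)
  expect_s3_class(enr, "enrichment_result")
  prom <- enr[enr$feature == "promoter", ]
  # all element probes are promoter probes; background is 60/400
  expect_equal(prom$observed_frac, 1)
  expect_equal(prom$background_frac, 60 / 400)
  expect_equal(prom$direction, "enrichment")
  expect_equal(
    prom$p_value,
    oracle_binom_upper(prom$observed, prom$n_probes, prom$background_frac),
    tolerance = 1e-10
  )
  ex <- enr[enr$feature == "exon", ]
  expect_equal(ex$direction, "depletion")
  expect_equal(
    ex$p_value,
    oracle_binom_lower(0, ex$n_probes, ex$background_frac),
    tolerance = 1e-10
  )
  # observed == expected: p >= 0.5 whichever tail is chosen
  p0 <- 60 / 400
  x_eq <- p0 * 40
  p_up <- stats::pbinom(x_eq - 1, 40, p0, lower.tail = FALSE)
  p_lo <- stats::pbinom(x_eq, 40, p0)
  expect_gte(max(p_up, p_lo), 0.5)
})

test_that("rank-sum comparisons agree with exhaustive enumeration", {
  out <- compare_gene_sets(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(out$p_value, 0.05) # 1 of choose(6,3) = 20 assignments

  for (seed in 1:15) {
    ab <- withr::with_seed(seed, {
      n1 <- sample(2:6, 1)
      n2 <- sample(2:6, 1)
      list(a = round(rnorm(n1), 3), b = round(rnorm(n2), 3))
    })
    for (alt in c("less", "greater", "two.sided")) {
      got <- compare_gene_sets(ab$a, ab$b, alternative = alt)$p_value
      want <- oracle_ranksum_p(ab$a, ab$b, alt)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }

  # identical sets: two-sided p of 1, exact even though everything is tied
  same <- compare_gene_sets(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_match(same$method, "enumeration")

  # invariance under monotone transforms of the pooled values
  a <- c(0.2, 1.5, 2.2)
  b <- c(0.7, 3.1, 4.0, 5.5)
  expect_equal(
    compare_gene_sets(a, b, "less")$p_value,
    compare_gene_sets(exp(a), exp(b), "less")$p_value
  )
  expect_error(compare_gene_sets(numeric(0), b), "non-empty")
})

test_that("track correlations behave at the trivial limits and support binning", {
  tr <- toy_track(c(1, 2, 3, 4, 5))
  tr2 <- tr
  tr2$score <- -tr$score
  expect_equal(track_correlation(tr, tr), 1)
  expect_equal(track_correlation(tr, tr2), -1)
  cst <- toy_track(rep(1, 5))
  expect_error(track_correlation(tr, cst), "zero variance")

  st <- small_study(73, chrom_lengths = c(chrA = 2e6), n_elements = c(A = 1, B = 1))
  sim_a <- simulate_damid(st$layout, st$arch, st$noise, factor = "A")
  sim_b <- simulate_damid(st$layout, st$arch, st$noise, factor = "B")
  a <- smooth_avg(sim_a$signal)
  b <- smooth_avg(sim_b$signal)
  r_probe <- track_correlation(a, b)
  r_bin <- track_correlation(a, b, bin_bp = 100000)
  expect_gt(r_probe, 0.5) # shared architecture drives strong correlation
  expect_gt(r_bin, r_probe) # binning averages out probe noise
})
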