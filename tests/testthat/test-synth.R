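test_that("probe layouts have the closed-form probe count and are seeded", {
  layout <- make_genome(c(chrA = 10000), probe_length = 50, spacing = 50, seed = 1)
  expect_equal(nrow(layout), 200) # floor((10000 - 50) / 50) + 1
  expect_true(all(layout$end <= 10000))
  expect_true(!is.unsorted(layout$start))
  expect_true(all(layout$gc >= 0 & layout$gc <= 50))

  again <- make_genome(c(chrA = 10000), probe_length = 50, spacing = 50, seed = 1)
  expect_identical(layout, again)
  other <- make_genome(c(chrA = 10000), probe_length = 50, spacing = 50, seed = 2)
  expect_false(identical(layout$gc, other$gc))

  expect_error(make_genome(c(chrA = -5)), "at least one probe")
  expect_error(make_genome(c(chrA = 1000), spacing = 0), "spacing")
  expect_error(make_genome(c(1000)), "named")
})

test_that("uniform GC model matches a uniform histogram within sampling error", {
  layout <- make_genome(c(chrA = 1e6), gc_model = "uniform", seed = 42)
  expect_gte(nrow(layout), 19999)
  obs <- table(factor(layout$gc, levels = 0:50))
  chi <- suppressWarnings(stats::chisq.test(obs, p = rep(1 / 51, 51)))
  expect_gt(chi$p.value, 0.001)
})

test_that("planted architectures hit the requested densities and containment", {
  layout <- make_genome(c(chrA = 15e6), seed = 3)
  arch <- plant_architecture(layout,
    arm_density = 0.6, center_density = 0.05,
    n_elements = c(A = 3, B = 3), n_detached = 2, seed = 4
  )
  arms <- arch$arms
  centers <- nedomains:::complement_intervals(arms, chrom_lengths(layout))
  domA <- arch$domains[arch$domains$factor == "A", ]
  arm_frac <- nedomains:::intersect_bp(domA, arms) / sum(arms$end - arms$start)
  center_frac <- nedomains:::intersect_bp(domA, centers) / sum(centers$end - centers$start)
  expect_lt(abs(arm_frac - 0.6), 0.05)
  expect_lt(abs(center_frac - 0.05), 0.05)

  # exclusive elements of one factor never overlap the other factor's domains
  for (fac in c("A", "B")) {
    el <- arch$elements[arch$elements$factor == fac, ]
    own <- arch$domains[arch$domains$factor == fac, ]
    oth <- arch$domains[arch$domains$factor != fac, ]
    expect_true(all(nedomains:::overlaps_any(el, own)))
    expect_false(any(nedomains:::overlaps_any(el, oth)))
  }

  # determinism and the no-element case
  again <- plant_architecture(layout,
    arm_density = 0.6, center_density = 0.05,
    n_elements = c(A = 3, B = 3), n_detached = 2, seed = 4
  )
  expect_identical(arch$domains, again$domains)
  none <- plant_architecture(layout, n_elements = c(A = 0, B = 0), seed = 4)
  expect_equal(nrow(none$elements), 0)

  expect_error(
    plant_architecture(layout, element_length = c(100, 300), min_probes = 10),
    "unplantable"
  )
})

test_that("simulated tracks follow the latent mean, null control and AR(1) law", {
  st <- small_study(5, chrom_lengths = c(chrA = 1e6), n_elements = c(A = 0, B = 0),
    n_detached = 2, sd = 0, n_reps = 1)
  noise0 <- noise_model(sd = 0, ar1 = 0, gc_slope = 0, n_reps = 1, seed = 9)
  sim <- simulate_damid(st$layout, st$arch, noise0, factor = "A")
  mu <- latent_mean(st$layout, st$arch, "A")
  expect_equal(sim$signal$rep1, mu)
  expect_equal(sim$null$rep1, rep(0, nrow(st$layout)))

  # null-control genome-wide mean within the CLT bound
  noise1 <- noise_model(sd = 1, ar1 = 0, gc_slope = 0, n_reps = 1, seed = 10)
  simn <- simulate_damid(st$layout, st$arch, noise1, factor = "A")
  n <- nrow(st$layout)
  expect_lt(abs(mean(simn$null$rep1)), 3 / sqrt(n))

  # lag-1 autocorrelation of residuals
  layout <- make_genome(c(chrA = 5e6), seed = 6)
  arch <- plant_architecture(layout, n_elements = c(A = 0, B = 0), n_detached = 0, seed = 7)
  noise5 <- noise_model(sd = 1, ar1 = 0.5, gc_slope = 0, n_reps = 1, seed = 8)
  simr <- simulate_damid(layout, arch, noise5, factor = "A")
  resid <- simr$signal$rep1 - latent_mean(layout, arch, "A")
  r1 <- stats::cor(resid[-1], resid[-length(resid)])
  expect_lt(abs(r1 - 0.5), 0.05)
})

test_that("mutant tracks drop detached regions to baseline", {
  st <- small_study(11, chrom_lengths = c(chrA = 2e6), n_elements = c(A = 1, B = 1))
  mu_wt <- latent_mean(st$layout, st$arch, "A", "wt")
  mu_mut <- latent_mean(st$layout, st$arch, "A", "mutant")
  det <- nedomains:::overlaps_any(st$layout, st$arch$detached)
  expect_true(any(det))
  expect_true(all(mu_mut[det] == 0))
  expect_true(all(mu_wt[det] > 0))
  expect_equal(mu_wt[!det], mu_mut[!det])
})

test_that("expression simulation honours fold, dispersion and group structure", {
  st <- small_study(13, chrom_lengths = c(chrA = 2e6), n_elements = c(A = 0, B = 0))
  genes <- make_genes(st$layout, n = 60, seed = 14)

  # deterministic at zero dispersion: exact fold ratio
  sim0 <- simulate_expression(genes, st$arch,
    baseline = 50, derepression_fold = 2,
    dispersion = 0, groups = c(wt = 2, mutant = 2), seed = 15
  )
  dere <- attr(sim0, "derepressed")
  expect_gt(length(dere), 0)
  w <- sim0[sim0$locus %in% dere, ]
  ratio <- mean(w$coverage[w$group == "mutant"]) / mean(w$coverage[w$group == "wt"])
  expect_equal(ratio, 2)

  # fold = 1 is a null: group means agree within sampling error
  sim1 <- simulate_expression(genes, st$arch,
    baseline = 50, derepression_fold = 1,
    dispersion = 0.05, groups = c(wt = 3, mutant = 3), seed = 16
  )
  mw <- mean(sim1$coverage[sim1$group == "wt"])
  mm <- mean(sim1$coverage[sim1$group == "mutant"])
  expect_lt(abs(mm - mw) / mw, 0.05)

  expect_error(
    simulate_expression(genes, st$arch, groups = c(wt = 1, mutant = 2)),
    ">= 2 samples"
  )
  bad <- genes
  bad$exons[[1]] <- bad$exons[[1]][0, ]
  expect_error(simulate_expression(bad, st$arch), "zero exons")
})

test_that("domain recovery improves monotonically with signal-to-noise", {
  layout <- make_genome(c(chrA = 3e6), seed = 21)
  arch <- plant_architecture(layout,
    n_elements = c(A = 0, B = 0), n_detached = 0, seed = 22
  )
  jacc <- vapply(c(1, 3, 6), function(sd) {
    noise <- noise_model(sd = sd, ar1 = 0.5, gc_slope = 0, n_reps = 2, seed = 23)
    sim <- simulate_damid(layout, arch, noise, factor = "A")
    avg <- smooth_avg(sim$signal)
    doms <- call_domains(window_scores(binarize(avg)), theta = 0.8)
    interval_jaccard(
      doms[, c("chrom", "start", "end")],
      arch$domains[arch$domains$factor == "A", c("chrom", "start", "end")]
    )
  }, numeric(1))
  expect_true(all(diff(jacc) <= 0))
})
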