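test_that("binarization maps signs with zero going negative", {
  tr <- toy_track(c(0.5, -0.2, 0))
  expect_equal(binarize(tr)$sign, c(1L, -1L, -1L))
  expect_equal(binarize(toy_track(c(2, 3)))$sign, c(1L, 1L))

  # antisymmetric away from exact zeros
  set.seed(41)
  x <- rnorm(50)
  x <- x[x != 0]
  expect_equal(binarize(toy_track(-x))$sign, -binarize(toy_track(x))$sign)
  expect_error(binarize(toy_track(c(1, NA))), "finite")
})

test_that("window scores have the closed-form count, range and anchoring", {
  tr <- toy_track(rep(0, 200))
  tr$sign <- rep(1L, 200)
  ws <- window_scores(tr)
  expect_equal(nrow(ws), 1)
  expect_equal(ws$value, 1)
  expect_equal(ws$start, 0)
  expect_equal(ws$end, 200 * 50)

  tr$sign <- c(rep(1L, 180), rep(-1L, 20))
  expect_equal(window_scores(tr)$value, 0.8) # (180 - 20) / 200

  tr2 <- toy_track(rep(0, 250))
  tr2$sign <- sample(c(-1L, 1L), 250, replace = TRUE)
  expect_equal(nrow(window_scores(tr2)), 51)

  # windows never span chromosomes; short chromosomes contribute none
  tr3 <- dplyr::bind_rows(
    random_sign_track(250, seed = 42),
    dplyr::mutate(random_sign_track(150, seed = 43), chrom = "chrB")
  )
  ws3 <- window_scores(tr3)
  expect_equal(unique(ws3$chrom), "chrA")
  expect_equal(nrow(ws3), 51)
  expect_true(all(ws3$value >= -1 & ws3$value <= 1))
})

test_that("FDR calibration follows its definition and the binomial null tail", {
  mk <- function(values) tibble::tibble(
    chrom = "chrA", start = seq_along(values), end = seq_along(values) + 1,
    first_probe = seq_along(values), value = values
  )
  # signal positive fraction 0.5, null positive fraction 0.02 at theta 0.8
  sig <- mk(c(rep(0.9, 50), rep(0, 50)))
  nul <- mk(c(rep(0.9, 2), rep(0, 98)))
  cal <- calibrate_fdr(sig, nul)
  row <- cal$table[cal$table$theta == 0.8, ]
  expect_equal(row$fdr, 0.04)
  expect_true(cal$default_theta_ok)

  # i.i.d. +/-1 null: P(window >= 0.8) is the exact binomial tail, which is
  # astronomically small, so large null sets contain no positive window
  tail_p <- oracle_binom_upper(180, 200, 0.5)
  expect_lt(tail_p, 1e-30)
  iid <- toy_track(rep(0, 100200))
  iid$sign <- withr::with_seed(44, sample(c(-1L, 1L), 100200, replace = TRUE))
  wsn <- window_scores(iid)
  expect_equal(sum(wsn$value >= 0.8), 0)

  # thresholds with no signal windows are excluded from selection
  none <- calibrate_fdr(mk(rep(0, 10)), mk(rep(0, 10)))
  expect_true(is.na(none$table$fdr[none$table$theta == 0.8]))
})

test_that("the domain caller is identical to brute-force window enumeration", {
  for (seed in c(1, 7, 23)) {
    n <- withr::with_seed(seed, sample(300:3000, 1))
    tr <- random_sign_track(n, seed = seed + 100)
    for (theta in c(0.6, 0.8)) {
      params <- domain_params(window = 100, theta = theta)
      got <- call_domains(window_scores(tr, params), params, theta = theta)
      want <- oracle_call_domains(tr, 100, theta)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("domain calling merges overlaps, respects theta monotonicity and conservation", {
  # overlapping positive spans merge into one domain
  ws <- tibble::tibble(
    chrom = "chrA", start = c(0, 50), end = c(10000, 10050),
    first_probe = c(1, 2), value = c(0.9, 0.85)
  )
  dom <- call_domains(ws, theta = 0.8)
  expect_equal(nrow(dom), 1)
  expect_equal(dom$start, 0)
  expect_equal(dom$end, 10050)

  # no window above threshold: empty set
  empty <- call_domains(ws, theta = 0.95)
  expect_equal(nrow(empty), 0)

  # raising theta never enlarges domains
  tr <- random_sign_track(4000, seed = 45)
  params <- domain_params(window = 100)
  wsr <- window_scores(tr, params)
  bp <- vapply(
    c(0.5, 0.7, 0.9),
    function(th) sum(call_domains(wsr, params, theta = th)$end -
      call_domains(wsr, params, theta = th)$start),
    numeric(1)
  )
  expect_true(all(diff(bp) <= 0))

  # domain bp + gap bp + terminal flanks = chromosome length
  doms <- call_domains(wsr, params, theta = 0.6)
  gs <- gaps_and_stats(doms, c(chrA = 200000))
  flank <- min(doms$start) + (200000 - max(doms$end))
  expect_equal(
    sum(doms$end - doms$start) + sum(gs$gaps$end - gs$gaps$start) + flank,
    200000
  )
})

test_that("gaps lie strictly between domains and statistics are exact", {
  doms <- tibble::tibble(
    chrom = "chrA", start = c(0L, 20000L), end = c(10000L, 30000L),
    label = "LAD"
  )
  gs <- gaps_and_stats(doms, c(chrA = 40000))
  expect_equal(nrow(gs$gaps), 1)
  expect_equal(gs$gaps$start, 10000)
  expect_equal(gs$gaps$end, 20000)
  expect_equal(gs$summary$coverage, 0.5)
  expect_equal(gs$summary$domain_median, 10000)

  single <- gaps_and_stats(doms[1, ], c(chrA = 40000))
  expect_equal(nrow(single$gaps), 0)
})

test_that("chromosome occupancy fractions and the autosome regression are exact", {
  cl <- c(chrI = 15072421, chrII = 12000000, chrIII = 9000000, chrX = 17718866)
  none <- chromosome_occupancy(
    tibble::tibble(chrom = character(), start = integer(), end = integer()),
    cl
  )
  expect_equal(none$table$fraction, rep(0, 4))

  doms <- tibble::tibble(chrom = "chrI", start = 0L, end = 5000000L)
  occ <- chromosome_occupancy(doms, cl)
  expect_equal(
    occ$table$fraction[occ$table$chrom == "chrI"],
    5000000 / 15072421,
    tolerance = 1e-12
  )
  expect_false(occ$table$autosome[occ$table$chrom == "chrX"])

  # fractions exactly linear in size give r = 1
  lin <- purrr::map_dfr(names(cl)[1:3], function(ch) {
    tibble::tibble(chrom = ch, start = 0L, end = as.integer(round(0.2 * cl[[ch]]^2 / 2e7)))
  })
  fit <- chromosome_occupancy(lin, cl)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_equal(glance(fit)$r, fit$r)
})

test_that("empirical false-discovery proportion stays near the ceiling on planted data", {
  # window-level FDP against planted truth at the calibrated threshold
  fdps <- vapply(1:5, function(seed) {
    st <- small_study(seed + 50,
      chrom_lengths = c(chrA = 3e6),
      n_elements = c(A = 0, B = 0), n_detached = 0, sd = 1
    )
    sim <- simulate_damid(st$layout, st$arch, st$noise, factor = "A")
    avg <- smooth_avg(sim$signal)
    nul <- smooth_avg(sim$null)
    params <- domain_params()
    ws <- window_scores(binarize(avg), params)
    wsn <- window_scores(binarize(nul), params)
    cal <- calibrate_fdr(ws, wsn, params)
    theta <- if (isTRUE(cal$default_theta_ok)) 0.8 else cal$selected_theta
    pos <- ws[ws$value >= theta, ]
    truth <- st$arch$domains[st$arch$domains$factor == "A", ]
    if (nrow(pos) == 0) {
      return(0)
    }
    # a positive window is false when it does not overlap planted truth
    mean(!nedomains:::overlaps_any(pos, truth))
  }, numeric(1))
  expect_true(all(fdps <= 0.05 + 0.02))
})
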