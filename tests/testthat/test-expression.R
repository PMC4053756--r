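test_that("exon expression is the median per-base coverage", {
  cov <- tibble::tibble(chrom = "chrA", pos = 0:2, depth = c(10, 10, 20))
  ex <- tibble::tibble(chrom = "chrA", start = 0L, end = 3L)
  expect_equal(exon_expression(cov, ex)$expression, 10)

  # even length takes the mean of the central pair
  cov2 <- tibble::tibble(chrom = "chrA", pos = 0:3, depth = c(1, 2, 3, 10))
  ex2 <- tibble::tibble(chrom = "chrA", start = 0L, end = 4L)
  expect_equal(exon_expression(cov2, ex2)$expression, 2.5)

  # constant coverage passes through; absent positions count as zero
  cov3 <- tibble::tibble(chrom = "chrA", pos = 0:9, depth = rep(7, 10))
  ex3 <- tibble::tibble(chrom = "chrA", start = 0L, end = 10L)
  expect_equal(exon_expression(cov3, ex3)$expression, 7)
  ex4 <- tibble::tibble(chrom = "chrA", start = 0L, end = 21L)
  expect_equal(exon_expression(cov3, ex4)$expression, 0)

  expect_error(
    exon_expression(cov, tibble::tibble(chrom = "chrA", start = 5L, end = 5L)),
    "zero-length"
  )
})

test_that("locus expression is an order-invariant median of exon values", {
  tbl <- tibble::tibble(locus = "g1", expression = c(5, 15, 10))
  expect_equal(locus_expression(tbl)$expression, 10)
  expect_equal(
    locus_expression(tbl[c(3, 1, 2), ])$expression,
    locus_expression(tbl)$expression
  )
  single <- tibble::tibble(locus = "g2", expression = 42)
  expect_equal(locus_expression(single)$expression, 42)

  # monotone in any single exon's value
  bumped <- tbl
  bumped$expression[1] <- 50
  expect_gte(
    locus_expression(bumped)$expression,
    locus_expression(tbl)$expression
  )
})

test_that("the SAM d statistic follows its formula", {
  # groups with means 10 and 20 and pooled standard error 2, s0 = 0.5
  a <- 10 + c(-1, 1) * sqrt(2)
  b <- 20 + c(-1, 1) * sqrt(2)
  m <- matrix(c(a, b), nrow = 1)
  colnames(m) <- c("a1", "a2", "b1", "b2")
  st <- nedomains:::sam_d_stat(m, 1:2, 3:4, 0.5)
  expect_equal(st$s, 2)
  expect_equal(st$d, 4) # (20 - 10) / (2 + 0.5)

  # invariant under adding a constant to every sample of a locus
  shifted <- nedomains:::sam_d_stat(m + 100, 1:2, 3:4, 0.5)
  expect_equal(shifted$d, st$d)
})

test_that("SAM selection is null-safe over repeated simulations", {
  nsig <- vapply(1:20, function(i) {
    m <- withr::with_seed(i, matrix(
      stats::rnorm(1000 * 5, 100, 10), 1000,
      dimnames = list(NULL, c("wt1", "wt2", "wt3", "mu1", "mu2"))
    ))
    fit <- sam_select(m,
      groups = c(wt1 = "wt", wt2 = "wt", wt3 = "wt", mu1 = "mu", mu2 = "mu"),
      group_a = "wt", group_b = "mu", delta = 4, seed = i
    )
    sum(fit$table$significant)
  }, numeric(1))
  expect_equal(stats::median(nsig), 0)

  m <- matrix(stats::rnorm(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  expect_error(
    sam_select(m, groups = c(a = "x", b = "x", c = "x", d = "y")),
    ">= 2 samples"
  )
})

test_that("SAM recovers planted fourfold loci with high recall and few false calls", {
  layout <- make_genome(c(chrA = 8e6, chrB = 7e6), seed = 81)
  arch <- plant_architecture(layout, n_elements = c(A = 0, B = 0), n_detached = 0, seed = 82)
  genes <- make_genes(layout, n = 1000, seed = 83)
  dere <- withr::with_seed(84, sample(genes$gene_id, 50))
  arch$detached <- genes[genes$gene_id %in% dere, c("chrom", "start", "end")]
  sim <- simulate_expression(genes, arch,
    baseline = 200, derepression_fold = 4,
    dispersion = 0.002, groups = c(wt = 3, mutant = 2), seed = 85
  )
  truth <- attr(sim, "derepressed")
  expect_equal(sort(truth), sort(dere))
  mat <- expression_matrix(sim)
  fit <- sam_select(mat, group_a = "wt", group_b = "mutant", delta = 4, seed = 86)
  sig <- fit$table$locus[fit$table$significant]
  expect_gte(mean(truth %in% sig), 0.9)
  expect_lte(sum(!(sig %in% truth)), 2)
  expect_true(all(fit$table$direction[fit$table$locus %in% sig] == "up"))
  expect_equal(glance(fit)$n_significant, length(sig))
})

test_that("fold changes report group-mean ratios with replicate-pair extremes", {
  mat <- tibble::tibble(
    locus = c("g1", "g2", "g3"),
    wt1 = c(10, 5, 0), wt2 = c(10, 5, 0),
    mu1 = c(20, 5, 3), mu2 = c(20, 5, 3)
  )
  groups <- c(wt1 = "wt", wt2 = "wt", mu1 = "mu", mu2 = "mu")
  fc <- fold_change_table(mat, groups = groups, group_a = "wt", group_b = "mu")
  expect_equal(fc$fold_change[1], 2)
  expect_equal(fc$fold_change[2], 1)
  expect_true(is.na(fc$fold_change[3]))
  expect_true(fc$undefined[3])
  expect_equal(fc$fc_min[1], 2)
  expect_equal(fc$fc_max[1], 2)
  expect_error(
    fold_change_table(mat, groups = groups, loci = character(0)),
    "non-empty"
  )
})

test_that("planted de-repression shows as a positive released-class fold change", {
  layout <- make_genome(c(chrA = 5e6), seed = 91)
  arch <- plant_architecture(layout, n_elements = c(A = 0, B = 0), n_detached = 4, seed = 92)
  genes <- make_genes(layout, n = 300, seed = 93)
  sim <- simulate_expression(genes, arch,
    baseline = 200, derepression_fold = 4,
    dispersion = 0.05, groups = c(wt = 3, mutant = 2), seed = 94
  )
  released <- attr(sim, "derepressed")
  expect_gt(length(released), 0)
  mat <- expression_matrix(sim)
  fc <- fold_change_table(mat, group_a = "wt", group_b = "mutant")
  lfc <- log2(fc$fold_change)
  med_released <- stats::median(lfc[fc$locus %in% released], na.rm = TRUE)
  med_other <- stats::median(lfc[!(fc$locus %in% released)], na.rm = TRUE)
  expect_gt(med_released, 0.5)
  expect_lt(abs(med_other), 0.2)
})
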