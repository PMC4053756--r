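#' Median per-base coverage over exons
#'
#' Exon expression is the median of the per-base coverage across the exon's
#' genomic range. Positions absent from the coverage table count as zero
#' coverage.
#'
#' @param coverage Tibble `chrom`, `pos` (0-based base position), `depth`,
#'   for one sample.
#' @param exons Tibble `chrom`, `start`, `end` plus identifier columns
#'   (e.g. `exon`, `locus`).
#' @return `exons` with an added `expression` column.
#' @export
exon_expression <- function(coverage, exons) {
  stopifnot_cols(coverage, c("chrom", "pos", "depth"), "coverage")
  stopifnot_cols(exons, c("chrom", "start", "end"), "exons")
  if (any(exons$end <= exons$start)) rlang::abort("zero-length exon")
  exons$expression <- purrr::pmap_dbl(
    exons[c("chrom", "start", "end")],
    function(chrom, start, end) {
      sel <- coverage$chrom == chrom & coverage$pos >= start & coverage$pos < end
      d <- coverage$depth[sel]
      width <- end - start
      stats::median(c(d, rep(0, width - length(d))))
    }
  )
  exons
}

#' Locus expression from exon values
#'
#' A locus's expression is the median of the expression values of its
#' distinct exons, so it is invariant to exon order and robust to a single
#' outlying exon.
#'
#' @param exon_values Tibble with a locus id column and an expression
#'   column (optionally one row per exon and sample).
#' @param value_col Expression column name.
#' @param locus_col Locus id column name.
#' @param sample_col Optional sample column; when present, medians are
#'   computed per locus and sample.
#' @return Tibble of per-locus medians (long if `sample_col` is present).
#' @export
locus_expression <- function(exon_values, value_col = "expression",
                             locus_col = "locus", sample_col = NULL) {
  stopifnot_cols(exon_values, c(locus_col, value_col), "exon values")
  by <- c(locus_col, sample_col)
  exon_values |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      expression = stats::median(.data[[value_col]]),
      .groups = "drop"
    )
}

#' Build a locus-by-sample expression matrix
#'
#' Convenience wrapper: quantile-normalizes an exon-by-sample table across
#' samples and collapses exons to per-locus medians.
#'
#' @param exon_long Long tibble with `locus`, `exon`, `sample`, `coverage`
#'   (e.g. the output of [simulate_expression()]).
#' @param quantile Whether to quantile-normalize exon values across samples
#'   first.
#' @return Wide tibble `locus` plus one column per sample, with the
#'   sample-to-group map (if present in `exon_long`) in attribute `groups`.
#' @export
expression_matrix <- function(exon_long, quantile = TRUE) {
  stopifnot_cols(exon_long, c("locus", "exon", "sample", "coverage"), "exon table")
  wide <- exon_long |>
    dplyr::select("locus", "exon", "sample", "coverage") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "coverage")
  samples <- setdiff(names(wide), c("locus", "exon"))
  if (quantile) {
    wide[samples] <- as.data.frame(quantile_normalize(as.matrix(wide[samples])))
  }
  mat <- wide |>
    tidyr::pivot_longer(dplyr::all_of(samples), names_to = "sample", values_to = "expression") |>
    locus_expression(sample_col = "sample") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "expression")
  groups <- NULL
  if ("group" %in% names(exon_long)) {
    map <- dplyr::distinct(exon_long, .data$sample, .data$group)
    groups <- stats::setNames(map$group, map$sample)[samples]
  }
  structure(mat, groups = groups)
}

sam_d_stat <- function(m, ia, ib, s0) {
  na <- length(ia)
  nb <- length(ib)
  ma <- rowMeans(m[, ia, drop = FALSE])
  mb <- rowMeans(m[, ib, drop = FALSE])
  ssa <- rowSums((m[, ia, drop = FALSE] - ma)^2)
  ssb <- rowSums((m[, ib, drop = FALSE] - mb)^2)
  s <- sqrt((1 / na + 1 / nb) * (ssa + ssb) / (na + nb - 2))
  list(d = (mb - ma) / (s + s0), s = s, mean_a = ma, mean_b = mb)
}

# Fudge-factor selection. "median" fixes s0 at the 50th percentile of the
# per-locus standard errors (the stable classic choice); "cv" scans the
# percentiles of {s_i} for the one minimizing the coefficient of variation
# of the d spread across s-quantile windows. The cv rule presumes the
# spread of d varies smoothly with s, which holds for typical microarray
# noise but can degenerate to an extreme percentile when s spans orders of
# magnitude while the mean differences do not scale with it.
choose_s0 <- function(m, ia, ib, s, rule = c("median", "cv")) {
  rule <- match.arg(rule)
  if (rule == "median") {
    return(stats::median(s))
  }
  cand <- unique(stats::quantile(s, probs = seq(0, 1, by = 0.05), names = FALSE))
  n_bins <- max(2L, min(20L, floor(length(s) / 50)))
  bin <- cut(rank(s, ties.method = "first"), breaks = n_bins, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- sam_d_stat(m, ia, ib, s0)$d
    v <- tapply(d, bin, stats::mad)
    if (mean(v) == 0) {
      return(Inf)
    }
    stats::sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cv)]
}

#' SAM-style selection of differentially expressed loci
#'
#' Computes a moderated d statistic per locus, `d = (mean_b - mean_a) /
#' (s + s0)`, where `s` is the pooled standard error and the fudge factor
#' `s0` is picked among the percentiles of the `s` distribution to minimize
#' the coefficient of variation of the d spread. Expected order statistics
#' are estimated from label permutations (full enumeration of all group
#' assignments when their number is small, otherwise a seeded sample), and
#' a locus is significant when its sorted d deviates from the
#' permutation-expected value by more than `delta`, using the standard
#' cut-point rule (all loci beyond the first exceedance on each side).
#'
#' @param expr Expression matrix from [expression_matrix()] (wide tibble
#'   `locus` + sample columns), or a numeric matrix with loci as rows.
#' @param groups Named character vector mapping sample names to groups;
#'   defaults to the matrix's `groups` attribute.
#' @param group_a,group_b Reference and test group labels; both need >= 2
#'   samples.
#' @param delta Significance threshold on |d - expected d| (> 0).
#' @param s0 Optional fixed fudge factor (skips the selection rule).
#' @param s0_rule `"median"` (default: s0 = median of the per-locus
#'   standard errors) or `"cv"` (percentile of s minimizing the coefficient
#'   of variation of the d spread).
#' @param max_perms Permutation budget; full enumeration is used when the
#'   number of distinct assignments does not exceed it.
#' @param seed Seed for permutation sampling (only used beyond full
#'   enumeration).
#' @return Object of class `sam_fit` with a per-locus `table` (d, s,
#'   expected d, delta deviation, significance, direction), the chosen
#'   `s0`, cut points, and permutation count.
#' @export
sam_select <- function(expr, groups = NULL, group_a = NULL, group_b = NULL,
                       delta = 4, s0 = NULL, s0_rule = c("median", "cv"),
                       max_perms = 1000, seed = 1) {
  if (delta <= 0) rlang::abort("delta must be > 0")
  if (is.data.frame(expr)) {
    groups <- groups %||% attr(expr, "groups")
    loci <- expr$locus
    m <- as.matrix(expr[setdiff(names(expr), "locus")])
  } else {
    m <- as.matrix(expr)
    loci <- rownames(m) %||% as.character(seq_len(nrow(m)))
  }
  if (is.null(groups)) rlang::abort("a sample-to-group map is required")
  groups <- groups[colnames(m)]
  group_a <- group_a %||% unique(groups)[1]
  group_b <- group_b %||% unique(groups)[2]
  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    rlang::abort("each group needs >= 2 samples")
  }
  m <- m[, c(ia, ib), drop = FALSE]
  ia <- seq_along(ia)
  ib <- length(ia) + seq_len(length(ib))
  n <- ncol(m)

  base <- sam_d_stat(m, ia, ib, 0)
  s0 <- s0 %||% choose_s0(m, ia, ib, base$s, rule = s0_rule)
  obs <- sam_d_stat(m, ia, ib, s0)

  combos <- utils::combn(n, length(ib))
  if (ncol(combos) > max_perms) {
    combos <- withr::with_seed(seed, combos[, sample(ncol(combos), max_perms), drop = FALSE])
  }
  perm_sorted <- apply(combos, 2, function(jb) {
    ja <- setdiff(seq_len(n), jb)
    sort(sam_d_stat(m, ja, jb, s0)$d)
  })
  dbar_sorted <- rowMeans(perm_sorted)

  ord <- order(obs$d)
  dsort <- obs$d[ord]
  dev <- dsort - dbar_sorted
  cutup <- if (any(dev > delta & dsort > 0)) min(dsort[dev > delta & dsort > 0]) else Inf
  cutlow <- if (any(-dev > delta & dsort < 0)) max(dsort[-dev > delta & dsort < 0]) else -Inf

  rank_pos <- match(seq_along(obs$d), ord)
  tab <- tibble::tibble(
    locus = loci,
    mean_a = obs$mean_a,
    mean_b = obs$mean_b,
    s = obs$s,
    d = obs$d,
    dbar = dbar_sorted[rank_pos],
    delta_dev = obs$d - dbar_sorted[rank_pos],
    significant = obs$d >= cutup | obs$d <= cutlow,
    direction = dplyr::case_when(
      obs$d >= cutup ~ "up",
      obs$d <= cutlow ~ "down",
      TRUE ~ "none"
    )
  )
  structure(
    list(
      table = tab, s0 = s0, delta = delta, cutup = cutup, cutlow = cutlow,
      n_perms = ncol(combos), groups = c(a = group_a, b = group_b)
    ),
    class = "sam_fit"
  )
}

#' @export
print.sam_fit <- function(x, ...) {
  cat("<sam_fit>\n")
  cat(sprintf(
    "  %d loci, %d permutations, s0 = %.4g, delta = %g\n",
    nrow(x$table), x$n_perms, x$s0, x$delta
  ))
  cat(sprintf(
    "  significant: %d (up %d, down %d)\n",
    sum(x$table$significant),
    sum(x$table$direction == "up"), sum(x$table$direction == "down")
  ))
  invisible(x)
}

#' Fold changes between groups with replicate-pair extremes
#'
#' Ratio of group means (test over reference) per locus, with the minimum
#' and maximum over all replicate pairings as an error range. A zero
#' reference mean flags the ratio undefined.
#'
#' @param expr Expression matrix (wide tibble `locus` + sample columns) with
#'   a `groups` attribute, or pass `groups` explicitly.
#' @param groups Named character vector mapping samples to groups.
#' @param group_a,group_b Reference and test group labels.
#' @param loci Optional locus subset (non-empty when supplied).
#' @return Tibble `locus`, `mean_a`, `mean_b`, `fold_change`, `fc_min`,
#'   `fc_max`, `undefined`.
#' @export
fold_change_table <- function(expr, groups = NULL, group_a = NULL,
                              group_b = NULL, loci = NULL) {
  groups <- groups %||% attr(expr, "groups")
  if (is.null(groups)) rlang::abort("a sample-to-group map is required")
  if (!is.null(loci)) {
    if (length(loci) == 0) rlang::abort("locus set must be non-empty")
    expr <- expr[expr$locus %in% loci, , drop = FALSE]
  }
  m <- as.matrix(expr[setdiff(names(expr), "locus")])
  groups <- groups[colnames(m)]
  group_a <- group_a %||% unique(groups)[1]
  group_b <- group_b %||% unique(groups)[2]
  a <- m[, groups == group_a, drop = FALSE]
  b <- m[, groups == group_b, drop = FALSE]
  pair_ratios <- function(bi, ai) {
    r <- as.vector(outer(bi, 1 / ai))
    r[is.finite(r)]
  }
  rng <- purrr::map(seq_len(nrow(m)), function(i) {
    r <- pair_ratios(b[i, ], a[i, ])
    if (length(r) == 0) c(NA_real_, NA_real_) else range(r)
  })
  tibble::tibble(
    locus = expr$locus,
    mean_a = rowMeans(a),
    mean_b = rowMeans(b),
    fold_change = ifelse(rowMeans(a) == 0, NA_real_, rowMeans(b) / rowMeans(a)),
    fc_min = purrr::map_dbl(rng, 1),
    fc_max = purrr::map_dbl(rng, 2),
    undefined = rowMeans(a) == 0
  )
}
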