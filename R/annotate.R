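#' Average a secondary signal around domain boundaries
#'
#' Aligns all domain left boundaries (optionally both edges, with the right
#' edge mirrored so positive offsets always point into the domain) and
#' averages a secondary probe-level track in fixed offset bins. The
#' secondary track can be any probe-level signal: a histone mark, another
#' DamID factor, or a synthetic step track.
#'
#' @param track Probe-level secondary signal.
#' @param domains A `domain_set` (>= 1 domain).
#' @param flank_bp Half-width of the profiled region around each boundary.
#' @param step_bp Offset bin width; a flank smaller than the step yields a
#'   single bin.
#' @param side `"left"` (default, matching the published analysis) or
#'   `"both"`.
#' @param col Score column of `track`.
#' @return Tibble `offset_start`, `offset_mid`, `mean_score`, `n_probes`;
#'   offsets are probe start minus boundary, negative outside the domain.
#' @export
boundary_metaprofile <- function(track, domains, flank_bp = 10000,
                                 step_bp = 500, side = c("left", "both"),
                                 col = "score") {
  side <- match.arg(side)
  if (nrow(domains) == 0) rlang::abort("no domains: cannot build a metaprofile")
  step_bp <- min(step_bp, 2 * flank_bp)
  n_bins <- max(1L, as.integer(ceiling(2 * flank_bp / step_bp)))
  sums <- numeric(n_bins)
  counts <- integer(n_bins)
  for (ch in unique(domains$chrom)) {
    d <- domains[domains$chrom == ch, , drop = FALSE]
    s <- track$start[track$chrom == ch]
    x <- track[[col]][track$chrom == ch]
    if (length(s) == 0) next
    bounds <- d$start
    signs <- rep(1, nrow(d))
    if (side == "both") {
      bounds <- c(bounds, d$end)
      signs <- c(signs, rep(-1, nrow(d)))
    }
    for (k in seq_along(bounds)) {
      b <- bounds[k]
      lo <- findInterval(b - flank_bp - 0.5, s) + 1L
      hi <- findInterval(b + flank_bp - 0.5, s)
      if (hi < lo) next
      off <- signs[k] * (s[lo:hi] - b)
      bin <- pmin(n_bins, pmax(1L, as.integer(floor((off + flank_bp) / step_bp)) + 1L))
      agg <- tapply(x[lo:hi], bin, sum)
      idx <- as.integer(names(agg))
      sums[idx] <- sums[idx] + as.vector(agg)
      tab <- table(bin)
      counts[as.integer(names(tab))] <- counts[as.integer(names(tab))] + as.vector(tab)
    }
  }
  tibble::tibble(
    offset_start = -flank_bp + (seq_len(n_bins) - 1) * step_bp,
    offset_mid = -flank_bp + (seq_len(n_bins) - 0.5) * step_bp,
    mean_score = ifelse(counts > 0, sums / counts, NA_real_),
    n_probes = counts
  )
}

#' Mean probe score over gene bodies
#'
#' Averages the scores of probes overlapping (by at least 1 bp) the region
#' between a gene's transcription start and end sites. The occupancy is
#' strand-independent (span based). Genes with no overlapping probes are
#' flagged missing; genes with a positive mean are classed as anchored to
#' the nuclear envelope.
#'
#' @param track Averaged probe track.
#' @param genes Gene-model tibble (`gene_id`, `chrom`, `start`, `end`, ...).
#' @param col Score column.
#' @return `genes` with added `occupancy`, `n_probes` and `anchored`
#'   columns.
#' @export
gene_occupancy <- function(track, genes, col = "score") {
  stopifnot_cols(genes, c("gene_id", "chrom", "start", "end"), "gene models")
  occupancy <- rep(NA_real_, nrow(genes))
  n_probes <- integer(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    ti <- which(track$chrom == ch)
    if (length(ti) == 0) next
    hits <- IRanges::findOverlaps(
      tbl_to_ir(genes[gi, , drop = FALSE]),
      tbl_to_ir(track[ti, , drop = FALSE])
    )
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (length(qh) == 0) next
    means <- tapply(track[[col]][ti][sh], qh, mean)
    cnts <- table(qh)
    occupancy[gi[as.integer(names(means))]] <- as.vector(means)
    n_probes[gi[as.integer(names(cnts))]] <- as.vector(cnts)
  }
  genes$occupancy <- occupancy
  genes$n_probes <- n_probes
  genes$anchored <- occupancy > 0
  genes
}

# Classify each probe into promoter / exon / intron / intergenic with the
# fixed precedence promoter > exon > intron. Promoters are strand-aware:
# `promoter_bp` upstream of the transcription start site.
classify_probes <- function(track, genes, promoter_bp = 3000) {
  promoters <- genes |>
    dplyr::mutate(
      pstart = ifelse(.data$strand == "+", .data$start - promoter_bp, .data$end),
      pend = ifelse(.data$strand == "+", .data$start, .data$end + promoter_bp)
    ) |>
    dplyr::transmute(
      chrom = .data$chrom,
      start = as.integer(pmax(0, .data$pstart)),
      end = as.integer(.data$pend)
    )
  exons <- genes |>
    dplyr::select("chrom", "exons") |>
    tidyr::unnest("exons")
  spans <- genes[c("chrom", "start", "end")]
  cls <- rep("intergenic", nrow(track))
  in_span <- overlaps_any(track, spans)
  cls[in_span] <- "intron"
  cls[overlaps_any(track, exons)] <- "exon"
  cls[overlaps_any(track, promoters)] <- "promoter"
  # probes in a gene span but in neither exon nor promoter are intronic only
  # if the gene has introns at that position; span-minus-exon is intron by
  # construction here since exons tile part of the span.
  factor(cls, levels = c("promoter", "exon", "intron", "intergenic"))
}

#' Promoter/exon/intron enrichment of element probes
#'
#' Compares the distribution of probes inside a set of elements across
#' genomic feature classes with the background distribution over the whole
#' probe universe, using one-sided exact binomial tests. The tail is chosen
#' by the sign of observed minus expected: upper tail for enrichment, lower
#' tail for depletion.
#'
#' @param track The full probe track (the probe universe).
#' @param elements Interval tibble (e.g. an `element_set`): probes
#'   overlapping these intervals are tested.
#' @param genes Gene models with `strand` and an `exons` list column.
#' @param promoter_bp Promoter extent upstream of the TSS (bp).
#' @return An `enrichment_result` tibble: one row per feature class with
#'   observed and background fractions, direction and one-sided binomial
#'   p-value.
#' @export
feature_enrichment <- function(track, elements, genes, promoter_bp = 3000) {
  cls <- classify_probes(track, genes, promoter_bp)
  inside <- overlaps_any(track, elements)
  n <- sum(inside)
  if (n == 0) rlang::abort("no probes fall inside the supplied elements")
  out <- purrr::map_dfr(c("promoter", "exon", "intron"), function(fc) {
    p0 <- mean(cls == fc)
    if (p0 <= 0 || p0 >= 1) {
      rlang::abort(sprintf("degenerate background fraction for class '%s'", fc))
    }
    x <- sum(cls[inside] == fc)
    enriched <- x / n >= p0
    p <- if (enriched) {
      stats::pbinom(x - 1, n, p0, lower.tail = FALSE)
    } else {
      stats::pbinom(x, n, p0)
    }
    tibble::tibble(
      feature = fc,
      n_probes = n,
      observed = x,
      observed_frac = x / n,
      background_frac = p0,
      direction = if (enriched) "enrichment" else "depletion",
      p_value = p
    )
  })
  structure(out, class = c("enrichment_result", class(out)))
}

#' Rank-sum comparison of two gene-set score distributions
#'
#' Wilcoxon rank-sum test. For small samples the p-value is exact: when the
#' number of group assignments is modest the full permutation distribution
#' of the rank sum is enumerated (valid with ties); otherwise untied small
#' samples use the exact Wilcoxon distribution. Large samples (20 or more
#' per group, or too many assignments) fall back to the tie-corrected
#' normal approximation.
#'
#' @param values_a,values_b Numeric vectors (non-empty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (alternative
#'   about `values_a` relative to `values_b`).
#' @param max_enum Enumerate the permutation distribution exactly while
#'   `choose(n_a + n_b, n_a)` does not exceed this.
#' @return One-row tibble: `statistic` (Mann-Whitney W for group a),
#'   `p_value`, group sizes, `method`.
#' @export
compare_gene_sets <- function(values_a, values_b,
                              alternative = c("two.sided", "less", "greater"),
                              max_enum = 20000) {
  alternative <- match.arg(alternative)
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  na <- length(values_a)
  nb <- length(values_b)
  if (na == 0 || nb == 0) {
    rlang::abort("both gene sets must be non-empty")
  }
  w_stat <- sum(rank(c(values_a, values_b))[seq_len(na)]) - na * (na + 1) / 2
  small <- na < 20 && nb < 20
  if (small && choose(na + nb, na) <= max_enum) {
    r <- rank(c(values_a, values_b))
    obs <- sum(r[seq_len(na)])
    all_st <- apply(utils::combn(na + nb, na), 2, function(ix) sum(r[ix]))
    p_le <- mean(all_st <= obs)
    p_ge <- mean(all_st >= obs)
    p <- switch(alternative,
      less = p_le,
      greater = p_ge,
      two.sided = min(1, 2 * min(p_le, p_ge))
    )
    method <- "exact enumeration"
  } else {
    exact <- small && !any(duplicated(c(values_a, values_b)))
    wt <- suppressWarnings(
      stats::wilcox.test(values_a, values_b,
        alternative = alternative,
        exact = exact, correct = !exact
      )
    )
    p <- wt$p.value
    method <- if (exact) "exact" else "normal approximation, tie-corrected"
  }
  tibble::tibble(
    statistic = w_stat,
    p_value = p,
    n_a = na,
    n_b = nb,
    alternative = alternative,
    method = method
  )
}

#' Pearson correlation between two tracks
#'
#' Correlates paired probe scores, optionally after averaging both tracks in
#' non-overlapping genomic bins (the chromosome-scale comparison used for
#' factor-vs-factor agreement).
#'
#' @param track_a,track_b Probe tracks over the identical probe set.
#' @param col Score column.
#' @param bin_bp Optional bin width for pre-binning via [bin_average()].
#' @param chrom_lengths Optional lengths for binning.
#' @return Pearson correlation coefficient (numeric scalar).
#' @export
track_correlation <- function(track_a, track_b, col = "score", bin_bp = NULL,
                              chrom_lengths = NULL) {
  if (!is.null(bin_bp)) {
    track_a <- bin_average(track_a, col = col, bin_bp = bin_bp, chrom_lengths = chrom_lengths)
    track_b <- bin_average(track_b, col = col, bin_bp = bin_bp, chrom_lengths = chrom_lengths)
    col <- "score"
  }
  check_same_probes(track_a, track_b)
  a <- track_a[[col]]
  b <- track_b[[col]]
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]
  b <- b[keep]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    rlang::abort("correlation undefined: zero variance in at least one track")
  }
  stats::cor(a, b)
}
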