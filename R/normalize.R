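#' GC-stratified robust standardization of probe log-ratios
#'
#' Within each GC-count bin, scores are centred on the bin median and scaled
#' by the bin's median absolute deviation times a robust scale constant
#' (1.4826 makes the scale consistent with the standard deviation for
#' Gaussian noise). Bins with fewer than `min_bin_n` probes are merged with
#' the nearest neighbouring bin; a zero MAD falls back to a scale of 1 with
#' a warning. This removes probe-behaviour effects that are a function of
#' GC content, such as a linear GC bias.
#'
#' @param track Probe-track tibble with a `gc` column.
#' @param cols Score columns to normalize (default: all score columns).
#' @param gc_bin Bin width in GC-count units.
#' @param min_bin_n Minimum probes per bin before merging.
#' @param scale_const Robust scale constant multiplying the MAD.
#' @return The track with the named columns standardized.
#' @examples
#' tr <- tibble::tibble(
#'   chrom = "c", start = c(0L, 50L, 100L), end = c(50L, 100L, 150L),
#'   gc = c(20L, 20L, 20L), score = c(1, 2, 3)
#' )
#' gc_normalize(tr)$score # (x - 2) / 1.4826
#' @export
gc_normalize <- function(track, cols = NULL, gc_bin = 1, min_bin_n = 50,
                         scale_const = 1.4826) {
  stopifnot_cols(track, c("chrom", "start", "gc"), "probe track")
  if (min_bin_n < 2) rlang::abort("min_bin_n must be >= 2")
  cols <- track_score_cols(track, cols)
  bin <- floor(track$gc / gc_bin)
  # merge undersized bins into the nearest (by GC value) adjacent bin
  counts <- table(bin)
  levels <- as.numeric(names(counts))
  n <- as.vector(counts)
  group <- seq_along(levels)
  while (length(levels) > 1 && any(n < min_bin_n)) {
    i <- which(n < min_bin_n)[1]
    j <- if (i == 1) {
      2
    } else if (i == length(levels)) {
      i - 1
    } else if (levels[i] - levels[i - 1] <= levels[i + 1] - levels[i]) {
      i - 1
    } else {
      i + 1
    }
    keep <- min(i, j)
    drop <- max(i, j)
    n[keep] <- n[keep] + n[drop]
    group[group == drop] <- keep
    group[group > drop] <- group[group > drop] - 1
    levels <- levels[-drop]
    n <- n[-drop]
  }
  bin_id <- group[match(bin, as.numeric(names(counts)))]
  warned <- FALSE
  for (col in cols) {
    x <- track[[col]]
    if (any(!is.finite(x))) rlang::abort(sprintf("non-finite scores in column '%s'", col))
    med <- tapply(x, bin_id, stats::median)
    scl <- scale_const * tapply(x, bin_id, stats::mad, constant = 1)
    if (any(scl == 0)) {
      if (!warned) {
        rlang::warn("zero MAD in at least one GC bin; using scale 1 there")
        warned <- TRUE
      }
      scl[scl == 0] <- 1
    }
    key <- as.character(bin_id)
    track[[col]] <- as.numeric((x - med[key]) / scl[key])
  }
  track
}

#' Median smoothing over fixed-width genomic windows
#'
#' Replaces each probe's value by the median of all probes (itself included)
#' whose start lies within half the window of its own start, per chromosome.
#' The default 300-bp window matches the smoothing used to produce MA2C
#' scores on a 50-bp tiling design.
#'
#' @param track Sorted probe-track tibble.
#' @param cols Score columns to smooth.
#' @param window_bp Full window width in bp (probes at start +/- window/2).
#' @return The track with smoothed score columns.
#' @export
median_smooth <- function(track, cols = NULL, window_bp = 300) {
  if (window_bp <= 0) rlang::abort("window_bp must be positive")
  if (nrow(track) == 0) {
    return(track)
  }
  cols <- track_score_cols(track, cols)
  half <- window_bp / 2
  idx_by_chrom <- split(seq_len(nrow(track)), track$chrom)
  for (idx in idx_by_chrom) {
    s <- track$start[idx]
    if (is.unsorted(s)) rlang::abort("track must be sorted by (chrom, start)")
    n <- length(s)
    lo <- findInterval(s - half - 0.5, s) + 1L
    hi <- findInterval(s + half + 0.5 - 1e-9, s)
    # uniform probe spacing makes the interior a fixed odd-size running
    # median, which runmed computes in C; chromosome ends keep the exact
    # truncated-window definition.
    spacing <- if (n > 1) diff(s[1:2]) else 0
    uniform <- n > 2 && all(diff(s) == spacing) && spacing > 0
    k <- if (uniform) 2L * as.integer(half %/% spacing) + 1L else 0L
    for (col in cols) {
      x <- track[[col]][idx]
      if (uniform && k > 1 && n >= k) {
        sm <- as.numeric(stats::runmed(x, k, endrule = "keep"))
        hk <- (k - 1L) %/% 2L
        edge <- c(seq_len(hk), seq(n - hk + 1L, n))
        sm[edge] <- vapply(edge, function(i) stats::median(x[lo[i]:hi[i]]), numeric(1))
      } else {
        sm <- vapply(
          seq_along(x),
          function(i) stats::median(x[lo[i]:hi[i]]),
          numeric(1)
        )
      }
      track[[col]][idx] <- sm
    }
  }
  track
}

#' Quantile normalization across replicate score vectors
#'
#' Each column's sorted values are replaced by the across-column mean of the
#' order statistics and reassigned by rank; ties receive the mean of their
#' tied positions. All outputs share one sorted multiset, making intensity
#' distributions directly comparable across replicates and strains.
#'
#' @param x A numeric matrix/data frame of score vectors, or a probe-track
#'   tibble (then `cols` selects the score columns).
#' @param cols Score columns when `x` is a probe track.
#' @return Object of the same shape with normalized values.
#' @examples
#' quantile_normalize(cbind(A = c(3, 1, 2), B = c(6, 4, 5)))
#' @export
quantile_normalize <- function(x, cols = NULL) {
  if (is.data.frame(x) && all(c("chrom", "start") %in% names(x))) {
    cols <- track_score_cols(x, cols)
    if (length(cols) < 2) rlang::abort("quantile normalization needs >= 2 score vectors")
    m <- as.matrix(x[cols])
    x[cols] <- as.data.frame(limma::normalizeQuantiles(m, ties = TRUE))
    return(x)
  }
  m <- as.matrix(x)
  if (ncol(m) < 2) rlang::abort("quantile normalization needs >= 2 score vectors")
  if (!is.numeric(m)) rlang::abort("scores must be numeric")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Average replicate score columns into one track
#'
#' Per-probe arithmetic mean of the replicate columns; the pairwise Pearson
#' correlation matrix between replicates is attached as the
#' `replicate_cor` attribute (and is reported by the pipeline log).
#'
#' @param track Probe-track tibble with replicate score columns.
#' @param cols Replicate columns to average.
#' @param out_col Name of the averaged column.
#' @return Track tibble with coordinates, `gc` (if present) and `out_col`.
#' @export
average_replicates <- function(track, cols = NULL, out_col = "score") {
  cols <- track_score_cols(track, cols)
  if (length(cols) < 1) rlang::abort("no replicate columns found")
  m <- as.matrix(track[cols])
  keep <- intersect(c("chrom", "start", "end", "gc"), names(track))
  out <- track[keep]
  out[[out_col]] <- rowMeans(m)
  attr(out, "replicate_cor") <- if (length(cols) > 1 && all(apply(m, 2, stats::sd) > 0)) {
    stats::cor(m)
  } else {
    diag(length(cols))
  }
  out
}

#' Average scores in non-overlapping genomic bins
#'
#' Mean score of probes whose start falls in each fixed-width bin; bins with
#' no probes are reported with `NA` scores. Used to reduce point density for
#' chromosome-scale views and binned correlations.
#'
#' @param track Probe-track tibble.
#' @param col Score column to average.
#' @param bin_bp Bin width in bp (> 0).
#' @param chrom_lengths Optional named lengths; defaults to the largest probe
#'   end per chromosome.
#' @return Tibble `chrom`, `start`, `end`, `score`, `n_probes`.
#' @export
bin_average <- function(track, col = "score", bin_bp = 100000, chrom_lengths = NULL) {
  if (bin_bp <= 0) rlang::abort("bin_bp must be positive")
  stopifnot_cols(track, c("chrom", "start", col), "probe track")
  cl <- chrom_lengths %||%
    tapply(track$end, track$chrom, max)
  purrr::map_dfr(names(cl), function(ch) {
    len <- unname(cl[[ch]])
    n_bins <- ceiling(len / bin_bp)
    if (n_bins == 0) {
      return(NULL)
    }
    d <- track[track$chrom == ch, , drop = FALSE]
    b <- floor(d$start / bin_bp) + 1L
    means <- rep(NA_real_, n_bins)
    counts <- integer(n_bins)
    if (nrow(d) > 0) {
      agg <- tapply(d[[col]], b, mean)
      means[as.integer(names(agg))] <- as.vector(agg)
      tab <- table(b)
      counts[as.integer(names(tab))] <- as.vector(tab)
    }
    tibble::tibble(
      chrom = ch,
      start = as.integer((seq_len(n_bins) - 1) * bin_bp),
      end = as.integer(pmin(seq_len(n_bins) * bin_bp, len)),
      score = means, n_probes = counts
    )
  })
}

#' Full MA2C-style normalization chain for a set of DamID tracks
#'
#' Applies, in order: GC-stratified robust standardization per replicate,
#' 300-bp median smoothing, quantile normalization jointly over all
#' replicates and backgrounds of all supplied tracks, and replicate
#' averaging. This is the probe-score preparation used before domain
#' calling.
#'
#' @param tracks Named list of probe-track tibbles over the identical probe
#'   set, each with replicate score columns.
#' @param gc_bin,min_bin_n,scale_const Passed to [gc_normalize()].
#' @param smooth_bp Passed to [median_smooth()].
#' @return Named list of averaged tracks (column `score`), each carrying the
#'   `replicate_cor` attribute.
#' @export
ma2c_normalize <- function(tracks, gc_bin = 1, min_bin_n = 50,
                           scale_const = 1.4826, smooth_bp = 300) {
  if (is.null(names(tracks))) rlang::abort("tracks must be a named list")
  norm <- purrr::map(tracks, function(tr) {
    gc_normalize(tr, gc_bin = gc_bin, min_bin_n = min_bin_n, scale_const = scale_const) |>
      median_smooth(window_bp = smooth_bp)
  })
  # joint quantile normalization over every replicate of every track
  all_cols <- purrr::imap(norm, function(tr, nm) {
    m <- as.matrix(tr[track_score_cols(tr)])
    colnames(m) <- paste(nm, colnames(m), sep = ".")
    m
  })
  joint <- quantile_normalize(do.call(cbind, all_cols))
  offset <- 0
  purrr::map(norm, function(tr) {
    cols <- track_score_cols(tr)
    tr[cols] <- as.data.frame(joint[, offset + seq_along(cols), drop = FALSE])
    offset <<- offset + length(cols)
    average_replicates(tr, cols)
  })
}
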