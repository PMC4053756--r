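# Shared fixtures and independent oracles for the test suite.

# A minimal sorted probe track on one chromosome.
toy_track <- function(scores, spacing = 50L, chrom = "chrA", gc = NULL) {
  n <- length(scores)
  tibble::tibble(
    chrom = chrom,
    start = (seq_len(n) - 1L) * spacing,
    end = (seq_len(n) - 1L) * spacing + spacing,
    gc = gc %||% rep(25L, n),
    score = scores
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Segmented random sign track: alternating high/low positive-probability
# blocks, so some windows pass a threshold and others do not.
random_sign_track <- function(n, seed, spacing = 50L) {
  withr::with_seed(seed, {
    signs <- integer(0)
    while (length(signs) < n) {
      len <- sample(50:600, 1)
      p <- sample(c(0.95, 0.7, 0.5, 0.2), 1)
      signs <- c(signs, ifelse(stats::runif(len) < p, 1L, -1L))
    }
    signs <- signs[seq_len(n)]
    tr <- toy_track(rep(0, n), spacing = spacing)
    tr$sign <- signs
    tr
  })
}

# Brute-force domain caller: enumerate every window, threshold, and merge
# spans by repeated pairwise union. Independent of the package's cumsum +
# grouped-merge implementation.
oracle_call_domains <- function(track, window, theta) {
  res <- list()
  for (ch in unique(track$chrom)) {
    d <- track[track$chrom == ch, , drop = FALSE]
    n <- nrow(d)
    if (n < window) next
    spans <- list()
    for (i in seq_len(n - window + 1L)) {
      v <- mean(d$sign[i:(i + window - 1L)])
      if (v >= theta) spans[[length(spans) + 1L]] <- c(d$start[i], d$end[i + window - 1L])
    }
    merged <- list()
    for (sp in spans) {
      repeat {
        hit <- which(vapply(
          merged,
          function(m2) sp[1] < m2[2] && m2[1] < sp[2],
          logical(1)
        ))
        if (length(hit) == 0) break
        sp <- c(min(sp[1], merged[[hit[1]]][1]), max(sp[2], merged[[hit[1]]][2]))
        merged[[hit[1]]] <- NULL
      }
      merged[[length(merged) + 1L]] <- sp
    }
    if (length(merged) > 0) {
      m <- do.call(rbind, merged)
      o <- order(m[, 1])
      res[[ch]] <- tibble::tibble(chrom = ch, start = m[o, 1], end = m[o, 2])
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  dplyr::bind_rows(res)
}

# Exact binomial tail sums from first principles (log-space choose).
oracle_binom_upper <- function(x, n, p) {
  if (x > n) {
    return(0)
  }
  k <- x:n
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)))
}
oracle_binom_lower <- function(x, n, p) {
  k <- 0:x
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)))
}

# Exact rank-sum p by enumeration of all group assignments.
oracle_ranksum_p <- function(a, b, alternative) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  obs <- sum(r[seq_len(na)])
  combs <- utils::combn(length(pooled), na)
  all_st <- apply(combs, 2, function(ix) sum(r[ix]))
  p_le <- mean(all_st <= obs)
  p_ge <- mean(all_st >= obs)
  switch(alternative,
    less = p_le,
    greater = p_ge,
    two.sided = min(1, 2 * min(p_le, p_ge))
  )
}

# Small simulated study used by several recovery tests.
small_study <- function(seed, chrom_lengths = c(chrA = 4e6, chrB = 3e6),
                        n_elements = c(A = 4, B = 4), n_detached = 3,
                        sd = 0.5, n_reps = 3, gc_slope = 0) {
  layout <- make_genome(chrom_lengths, seed = seed)
  arch <- plant_architecture(layout,
    n_elements = n_elements,
    n_detached = n_detached, seed = seed + 10
  )
  noise <- noise_model(
    sd = sd, ar1 = 0.5, gc_slope = gc_slope,
    n_reps = n_reps, seed = seed + 20
  )
  list(layout = layout, arch = arch, noise = noise)
}

# Median-smoothed, replicate-averaged track (the score scale element
# thresholds refer to).
smooth_avg <- function(track) average_replicates(median_smooth(track))
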