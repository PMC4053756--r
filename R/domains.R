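#' Domain-calling parameters
#'
#' Defaults follow the published procedure: 200-probe windows (about 10 kb
#' on a 50-bp design) sliding one probe at a time, a binary window threshold
#' of 0.8, and a 5% empirical false discovery rate ceiling.
#'
#' @param window Window size in probes (>= 2).
#' @param offset Window slide in probes.
#' @param theta Binary window threshold in (0, 1].
#' @param fdr FDR ceiling in (0, 1).
#' @param theta_grid Candidate thresholds scanned by [calibrate_fdr()].
#' @return List of class `domain_params`.
#' @export
domain_params <- function(window = 200, offset = 1, theta = 0.8, fdr = 0.05,
                          theta_grid = seq(0.05, 1, by = 0.05)) {
  if (window < 2) rlang::abort("window must be >= 2 probes")
  if (offset < 1) rlang::abort("offset must be >= 1 probe")
  if (theta <= 0 || theta > 1) rlang::abort("theta must lie in (0, 1]")
  if (fdr <= 0 || fdr >= 1) rlang::abort("fdr ceiling must lie in (0, 1)")
  structure(
    list(window = window, offset = offset, theta = theta, fdr = fdr, theta_grid = theta_grid),
    class = "domain_params"
  )
}

#' Binarize probe scores to +1/-1
#'
#' Positive scores map to +1, negative to -1. A score of exactly zero maps
#' to -1: the conservative choice, so ambiguous probes never inflate
#' domains.
#'
#' @param track Probe-track tibble.
#' @param col Score column.
#' @return The track with an integer `sign` column.
#' @export
binarize <- function(track, col = "score") {
  stopifnot_cols(track, col, "probe track")
  if (any(!is.finite(track[[col]]))) rlang::abort("scores must be finite")
  track$sign <- ifelse(track[[col]] > 0, 1L, -1L)
  track
}

#' Sliding-window means of binarized probe values
#'
#' Averages the +1/-1 probe signs in fixed-size probe windows sliding by
#' `offset` probes. Windows never span chromosomes; a chromosome with fewer
#' probes than the window contributes no windows. Each window is anchored at
#' its first probe: its genomic span runs from the first probe's start to
#' the last probe's end.
#'
#' @param track Output of [binarize()] (needs a `sign` column).
#' @param params A [domain_params()].
#' @return Tibble `chrom`, `start`, `end`, `first_probe`, `value` with one
#'   row per window; `value` lies in \[-1, 1\].
#' @export
window_scores <- function(track, params = domain_params()) {
  stopifnot_cols(track, c("chrom", "start", "end", "sign"), "binarized track")
  w <- params$window
  purrr::map_dfr(split(track, factor(track$chrom, unique(track$chrom))), function(d) {
    n <- nrow(d)
    if (n < w) {
      return(NULL)
    }
    cs <- cumsum(d$sign)
    first <- seq(1L, n - w + 1L, by = params$offset)
    value <- (cs[first + w - 1L] - c(0, cs)[first]) / w
    tibble::tibble(
      chrom = d$chrom[1],
      start = d$start[first],
      end = d$end[first + w - 1L],
      first_probe = first,
      value = value
    )
  })
}

#' Calibrate the window threshold against a null control
#'
#' The same binarize-and-window procedure applied to a control
#' self-comparison track (freely diffusing Dam over itself) estimates how
#' many windows exceed a threshold by chance. For every candidate threshold
#' the empirical FDR is the fraction of null windows at or above it divided
#' by the fraction of signal windows at or above it, capped at 1. The
#' selected threshold is the smallest grid value whose FDR is below the
#' ceiling; whether the conventional default of 0.8 also satisfies the
#' ceiling is reported alongside.
#'
#' @param signal_windows,null_windows Window tibbles from [window_scores()],
#'   computed by the identical procedure.
#' @param params A [domain_params()].
#' @return Object of class `fdr_calibration`: the FDR table, the selected
#'   threshold, and the default-threshold check. `NA` FDR marks thresholds
#'   with no signal windows (excluded from selection).
#' @export
calibrate_fdr <- function(signal_windows, null_windows, params = domain_params()) {
  grid <- sort(unique(c(params$theta_grid, params$theta)))
  tab <- purrr::map_dfr(grid, function(th) {
    sf <- mean(signal_windows$value >= th)
    nf <- mean(null_windows$value >= th)
    tibble::tibble(
      theta = th,
      signal_frac = sf,
      null_frac = nf,
      fdr = if (sf == 0) NA_real_ else min(1, nf / sf)
    )
  })
  ok <- !is.na(tab$fdr) & tab$fdr < params$fdr
  selected <- if (any(ok)) tab$theta[which(ok)[1]] else NA_real_
  drow <- tab[tab$theta == params$theta, ]
  structure(
    list(
      table = tab,
      selected_theta = selected,
      default_theta = params$theta,
      default_theta_fdr = drow$fdr[1],
      default_theta_ok = isTRUE(drow$fdr[1] < params$fdr),
      ceiling = params$fdr
    ),
    class = "fdr_calibration"
  )
}

#' @export
print.fdr_calibration <- function(x, ...) {
  cat("<fdr_calibration>\n")
  cat(sprintf("  ceiling: %.3g\n", x$ceiling))
  cat(sprintf("  selected theta: %s\n", format(x$selected_theta)))
  cat(sprintf(
    "  default theta %.2f: FDR %s (%s)\n",
    x$default_theta, format(x$default_theta_fdr),
    if (isTRUE(x$default_theta_ok)) "passes" else "fails"
  ))
  invisible(x)
}

#' Call associated domains from window scores
#'
#' Windows at or above the threshold are converted to genomic spans (first
#' probe start to last probe end) and any overlapping (>= 1 bp) spans are
#' joined into domains. Abutting spans that share no base are kept separate.
#'
#' @param windows Window tibble from [window_scores()].
#' @param params A [domain_params()].
#' @param theta Threshold; defaults to `params$theta`. Pass
#'   the selected threshold of a [calibrate_fdr()] object to use the
#'   calibrated value.
#' @param label Domain label (e.g. `"LAD"`, `"EAD"`).
#' @return A `domain_set` tibble: `chrom`, `start`, `end`, `label`,
#'   `n_probes`, `n_windows`, `score` (mean window value, one row per
#'   domain), with calling parameters in attributes. May be empty.
#' @export
call_domains <- function(windows, params = domain_params(), theta = NULL,
                         label = "domain") {
  theta <- theta %||% params$theta
  if (is.na(theta)) rlang::abort("no threshold available (calibration selected none)")
  pos <- windows[windows$value >= theta, , drop = FALSE]
  if (nrow(pos) == 0) {
    out <- tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      label = character(), n_probes = integer(), n_windows = integer(),
      score = numeric()
    )
    return(structure(out, class = c("domain_set", class(out)), params = params, theta = theta, label = label))
  }
  out <- pos |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      grp = cumsum(.data$start >= dplyr::lag(cummax(.data$end), default = -1L))
    ) |>
    dplyr::group_by(.data$chrom, .data$grp) |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      n_probes = as.integer(max(.data$first_probe) + params$window - 1L - min(.data$first_probe) + 1L),
      n_windows = dplyr::n(),
      score = mean(.data$value),
      .groups = "drop"
    ) |>
    dplyr::select(-"grp") |>
    dplyr::mutate(label = label, .after = "end") |>
    dplyr::arrange(.data$chrom, .data$start)
  structure(out, class = c("domain_set", class(out)), params = params, theta = theta, label = label)
}

#' Gaps between domains and coverage statistics
#'
#' Gaps are the intervals strictly between consecutive domains on the same
#' chromosome; chromosome termini are not gaps. The summary reports counts,
#' genome coverage (domain bp over genome bp) and size quartiles for both
#' domains and gaps.
#'
#' @param domains A `domain_set` (or tibble with `chrom`, `start`, `end`).
#' @param layout Probe layout or named chromosome lengths.
#' @return List with `gaps` (tibble) and `summary` (one-row tibble).
#' @export
gaps_and_stats <- function(domains, layout) {
  cl <- as_chrom_lengths(layout)
  gaps <- domains |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(
      gap_start = .data$end[-dplyr::n()],
      gap_end = .data$start[-1]
    ) |>
    dplyr::filter(.data$gap_end > .data$gap_start) |>
    dplyr::rename(start = "gap_start", end = "gap_end")
  dsize <- domains$end - domains$start
  gsize <- gaps$end - gaps$start
  q <- function(x) {
    if (length(x) == 0) {
      return(c(NA_real_, NA_real_, NA_real_))
    }
    unname(stats::quantile(x, c(0.25, 0.5, 0.75)))
  }
  dq <- q(dsize)
  gq <- q(gsize)
  summary <- tibble::tibble(
    n_domains = nrow(domains),
    n_gaps = nrow(gaps),
    domain_bp = sum(dsize),
    genome_bp = sum(cl),
    coverage = sum(dsize) / sum(cl),
    domain_q25 = dq[1], domain_median = dq[2], domain_q75 = dq[3],
    gap_q25 = gq[1], gap_median = gq[2], gap_q75 = gq[3]
  )
  list(gaps = gaps, summary = summary)
}

#' Per-chromosome domain occupancy and size regression
#'
#' Fraction of each chromosome covered by domains, with a least-squares fit
#' of fraction against chromosome size over the autosomes. The X chromosome
#' is reported but excluded from the regression.
#'
#' @param domains A `domain_set`.
#' @param layout Probe layout or named chromosome lengths.
#' @param autosome_pattern Regular expression identifying non-autosomes by
#'   chromosome name.
#' @return Object of class `occupancy_fit`: per-chromosome table plus
#'   `slope`, `intercept` and Pearson `r` (all `NA` when fewer than two
#'   autosomes are available).
#' @export
chromosome_occupancy <- function(domains, layout, autosome_pattern = "X") {
  cl <- as_chrom_lengths(layout)
  dom_bp <- tapply(domains$end - domains$start, domains$chrom, sum)
  tab <- tibble::tibble(
    chrom = names(cl),
    size = unname(cl),
    domain_bp = as.numeric(dom_bp[names(cl)]),
    autosome = !grepl(autosome_pattern, names(cl), ignore.case = TRUE)
  ) |>
    dplyr::mutate(
      domain_bp = ifelse(is.na(.data$domain_bp), 0, .data$domain_bp),
      fraction = .data$domain_bp / .data$size
    )
  auto <- tab[tab$autosome, ]
  if (nrow(auto) >= 2 && stats::sd(auto$fraction) > 0) {
    fit <- stats::lm(fraction ~ size, data = auto)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r <- stats::cor(auto$size, auto$fraction)
  } else {
    slope <- intercept <- r <- NA_real_
  }
  structure(
    list(table = tab, slope = slope, intercept = intercept, r = r),
    class = "occupancy_fit"
  )
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat("<occupancy_fit>\n")
  print(x$table)
  cat(sprintf(
    "  autosome fit: fraction = %.3g + %.3g * size, r = %.3f\n",
    x$intercept, x$slope, x$r
  ))
  invisible(x)
}
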