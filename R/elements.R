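#' Parameters for exclusive-element and detached-region calling
#'
#' Defaults follow the published rule: probes scoring at least 1 on the
#' factor of interest and below 0 on the other factor, with at least 10
#' qualifying probes each separated by at most 500 bp from the neighbouring
#' qualifying probe.
#'
#' @param min_score Minimum own-track score for a qualifying probe.
#' @param max_other Exclusive upper bound on the other track's score.
#' @param min_probes Minimum qualifying probes per element (>= 2).
#' @param max_gap Maximum start-to-start separation (bp) between
#'   consecutive qualifying probes in a chain.
#' @return List of class `element_params`.
#' @export
element_params <- function(min_score = 1.0, max_other = 0.0, min_probes = 10,
                           max_gap = 500) {
  if (min_probes < 2) rlang::abort("min_probes must be >= 2")
  if (max_gap <= 0) rlang::abort("max_gap must be positive")
  structure(
    list(
      min_score = min_score, max_other = max_other,
      min_probes = min_probes, max_gap = max_gap
    ),
    class = "element_params"
  )
}

# Chain qualifying probes: maximal runs whose consecutive start-to-start
# distance is <= max_gap; runs with >= min_probes probes become intervals
# [first qualifying start, last qualifying end). Non-qualifying probes
# inside a chain never break it -- only spacing does.
chain_probes <- function(track, qualifies, params, label) {
  q <- track[qualifies, c("chrom", "start", "end"), drop = FALSE]
  if (nrow(q) == 0) {
    out <- tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      label = character(), n_probes = integer()
    )
    return(structure(out, class = c("element_set", class(out)), params = params, label = label))
  }
  out <- q |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      new_chain = c(TRUE, diff(.data$start) > params$max_gap),
      chain = cumsum(.data$new_chain)
    ) |>
    dplyr::group_by(.data$chrom, .data$chain) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      n_probes = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::filter(.data$n_probes >= params$min_probes) |>
    dplyr::select(-"chain") |>
    dplyr::mutate(label = label, .after = "end") |>
    dplyr::arrange(.data$chrom, .data$start)
  structure(out, class = c("element_set", class(out)), params = params, label = label)
}

#' Call factor-exclusive elements
#'
#' Finds regions whose probes score high on one factor's track while the
#' other factor's track stays negative: qualifying probes satisfy
#' `own >= min_score` and `other < max_other`; maximal chains of qualifying
#' probes separated by at most `max_gap` bp (start-to-start) with at least
#' `min_probes` members are emitted as elements spanning the first
#' qualifying probe's start to the last one's end.
#'
#' @param track_own,track_other Averaged probe tracks over the identical
#'   probe set.
#' @param params An [element_params()].
#' @param col Score column in both tracks.
#' @param label Element label (e.g. `"B-only"`).
#' @return An `element_set` tibble: `chrom`, `start`, `end`, `label`,
#'   `n_probes` (qualifying probes per element).
#' @export
call_exclusive_elements <- function(track_own, track_other,
                                    params = element_params(),
                                    col = "score", label = "exclusive") {
  check_same_probes(track_own, track_other)
  qualifies <- track_own[[col]] >= params$min_score &
    track_other[[col]] < params$max_other
  chain_probes(track_own, qualifies, params, label)
}

#' Per-probe difference between two tracks
#'
#' @param track_a,track_b Probe tracks over the identical probe set.
#' @param col Score column.
#' @param out_col Name of the output column.
#' @return A track tibble with `out_col = a - b`.
#' @export
difference_track <- function(track_a, track_b, col = "score", out_col = "score") {
  check_same_probes(track_a, track_b)
  keep <- intersect(c("chrom", "start", "end", "gc"), names(track_a))
  out <- track_a[keep]
  out[[out_col]] <- track_a[[col]] - track_b[[col]]
  out
}

#' Call genotype-dependent detached regions
#'
#' Regions whose association drops in a mutant relative to wild type:
#' applies the exclusive-element chaining machinery to the wild-type minus
#' mutant difference track, with `min_score` acting as the detachment
#' threshold and no condition on a second track. Swapping the arguments
#' finds regions gained in the mutant instead.
#'
#' @param track_wt,track_mut Jointly normalized averaged tracks over the
#'   identical probe set.
#' @param params An [element_params()] (`max_other` unused here).
#' @param col Score column.
#' @param label Region label.
#' @return An `element_set` tibble.
#' @export
call_detached_regions <- function(track_wt, track_mut,
                                  params = element_params(),
                                  col = "score", label = "detached") {
  diff <- difference_track(track_wt, track_mut, col = col)
  chain_probes(diff, diff$score >= params$min_score, params, label)
}
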