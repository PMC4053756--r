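# Interval algebra over plain (chrom, start, end) tibbles, 0-based half-open.
# IRanges does the set arithmetic; these wrappers keep the tidy surface.

tbl_to_ir <- function(df) {
  # half-open [start, end) -> 1-based closed [start+1, end]
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

ir_to_tbl <- function(ir, chrom) {
  tibble::tibble(
    chrom = chrom,
    start = IRanges::start(ir) - 1L,
    end = IRanges::end(ir)
  )
}

#' Merge overlapping intervals
#'
#' Intervals sharing at least 1 bp are merged; abutting intervals (0 bp
#' overlap) are kept separate, matching the domain-joining rule.
#'
#' @param df Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @return Tibble of disjoint sorted intervals.
#' @keywords internal
merge_overlapping <- function(df) {
  if (nrow(df) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      ir <- IRanges::reduce(tbl_to_ir(d), min.gapwidth = 0L)
      tibble::tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$start)
}

# Logical vector: does each row of `query` overlap (>= 1 bp) any row of
# `subject` on the same chromosome?
overlaps_any <- function(query, subject) {
  out <- logical(nrow(query))
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(out)
  }
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    s <- subject[subject$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0) next
    hits <- IRanges::overlapsAny(tbl_to_ir(query[qi, , drop = FALSE]), tbl_to_ir(s))
    out[qi] <- hits
  }
  out
}

# Total intersection width (bp) between two interval sets.
intersect_bp <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(0)
  }
  total <- 0
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- IRanges::reduce(tbl_to_ir(a[a$chrom == ch, , drop = FALSE]))
    ib <- IRanges::reduce(tbl_to_ir(b[b$chrom == ch, , drop = FALSE]))
    total <- total + sum(IRanges::width(IRanges::intersect(ia, ib)))
  }
  total
}

interval_bp <- function(df) {
  if (nrow(df) == 0) {
    return(0)
  }
  sum(merge_overlapping(df) |> dplyr::mutate(w = .data$end - .data$start) |> dplyr::pull("w"))
}

#' Jaccard index between two interval sets
#'
#' Base-pair intersection over union, computed after merging each set.
#'
#' @param a,b Tibbles with `chrom`, `start`, `end`.
#' @return A number in \[0, 1\]; 1 when both sets are empty.
#' @export
interval_jaccard <- function(a, b) {
  inter <- intersect_bp(a, b)
  uni <- interval_bp(a) + interval_bp(b) - inter
  if (uni == 0) {
    return(1)
  }
  inter / uni
}

# Complement of `df` within [0, chrom_lengths[chrom]) for every chromosome
# named in chrom_lengths.
complement_intervals <- function(df, chrom_lengths) {
  purrr::map_dfr(names(chrom_lengths), function(ch) {
    len <- unname(chrom_lengths[[ch]])
    d <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(d) == 0) {
      return(tibble::tibble(chrom = ch, start = 0L, end = as.integer(len)))
    }
    ir <- IRanges::gaps(
      IRanges::reduce(tbl_to_ir(d)),
      start = 1L, end = as.integer(len)
    )
    ir_to_tbl(ir, ch)
  })
}

stopifnot_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "%s is missing required column(s): %s", what, paste(missing, collapse = ", ")
    ))
  }
}

# Numeric score columns of a probe track: everything numeric that is not a
# coordinate or the GC sidecar column.
track_score_cols <- function(track, cols = NULL) {
  if (!is.null(cols)) {
    stopifnot_cols(track, cols, "probe track")
    return(cols)
  }
  cand <- setdiff(names(track), c("chrom", "start", "end", "gc"))
  cand[vapply(track[cand], is.numeric, logical(1))]
}

# Shared probe-grid check for operations pairing two tracks.
check_same_probes <- function(a, b) {
  if (nrow(a) != nrow(b) || !identical(a$chrom, b$chrom) || !identical(a$start, b$start)) {
    rlang::abort("tracks must be defined over the identical probe set")
  }
  invisible(TRUE)
}
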