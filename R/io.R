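# Readers and writers for the plain-text formats the pipeline speaks:
# bedGraph score tracks with a GC sidecar, BED interval sets, BED12 gene
# models, two-column gene-set tables, and YAML run configs.

#' Read a probe track from bedGraph plus a GC sidecar
#'
#' The bedGraph supplies (chrom, start, end, score); the sidecar TSV
#' (header `chrom start end gc`) supplies the per-probe GC count, joined by
#' (chrom, start, end). Unsorted input is sorted with a warning; malformed
#' intervals and unmatched probes are errors.
#'
#' @param path bedGraph file (track/comment lines ignored).
#' @param sidecar GC sidecar TSV; `NULL` for a track without GC counts.
#' @param col Name for the score column.
#' @return A probe-track tibble.
#' @export
read_probe_track <- function(path, sidecar = NULL, col = "score") {
  lines <- readLines(path)
  keep <- !grepl("^(track|#)", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "malformed bedGraph line %d in %s: expected 4 tab-separated fields",
      which(keep)[bad[1]], path
    ))
  }
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  track <- tibble::tibble(
    chrom = m[, 1],
    start = as.integer(m[, 2]),
    end = as.integer(m[, 3])
  )
  track[[col]] <- as.numeric(m[, 4])
  bad <- which(is.na(track$start) | is.na(track$end) | is.na(track[[col]]) |
    track$end <= track$start)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "malformed bedGraph line %d in %s: bad coordinates or score",
      which(keep)[bad[1]], path
    ))
  }
  resorted <- dplyr::arrange(track, .data$chrom, .data$start)
  if (!identical(resorted$start, track$start) || !identical(resorted$chrom, track$chrom)) {
    rlang::warn(sprintf("unsorted bedGraph %s: sorting by (chrom, start)", path))
    track <- resorted
  }
  if (!is.null(sidecar)) {
    gc <- readr::read_tsv(sidecar, show_col_types = FALSE, progress = FALSE)
    stopifnot_cols(gc, c("chrom", "start", "end", "gc"), "GC sidecar")
    track <- dplyr::left_join(track, gc, by = c("chrom", "start", "end"))
    miss <- which(is.na(track$gc))
    if (length(miss) > 0) {
      rlang::abort(sprintf(
        "GC sidecar %s is missing %d probe(s); first: %s:%d-%d",
        sidecar, length(miss), track$chrom[miss[1]], track$start[miss[1]], track$end[miss[1]]
      ))
    }
    track <- track[c("chrom", "start", "end", "gc", col)]
  }
  track
}

#' Write a probe track as bedGraph (plus optional GC sidecar)
#'
#' @param track Probe-track tibble.
#' @param path Output bedGraph path.
#' @param col Score column to write.
#' @param sidecar Optional path for the GC sidecar TSV.
#' @return `path`, invisibly.
#' @export
write_probe_track <- function(track, path, col = "score", sidecar = NULL) {
  stopifnot_cols(track, c("chrom", "start", "end", col), "probe track")
  readr::write_tsv(
    tibble::tibble(
      chrom = track$chrom, start = track$start, end = track$end,
      score = track[[col]]
    ),
    path,
    col_names = FALSE, progress = FALSE
  )
  if (!is.null(sidecar)) {
    stopifnot_cols(track, "gc", "probe track")
    readr::write_tsv(track[c("chrom", "start", "end", "gc")], sidecar, progress = FALSE)
  }
  invisible(path)
}

#' Write an interval set as BED
#'
#' 0-based half-open BED ordered by (chrom, start). The score column holds
#' the mean window value scaled to 0--1000 for domain sets, and the
#' qualifying-probe count for element sets. Calling parameters recorded in
#' the object's attributes are echoed as `#`-prefixed header comments.
#' Overlapping intervals violate the set's contract and are refused.
#'
#' @param x A `domain_set`, `element_set`, or plain interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  stopifnot_cols(x, c("chrom", "start", "end"), "interval set")
  x <- dplyr::arrange(x, .data$chrom, .data$start)
  overlap <- x |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(bad = .data$start < dplyr::lag(cummax(.data$end), default = -1L)) |>
    dplyr::pull("bad")
  if (any(overlap)) {
    rlang::abort("contract violation: interval set contains overlapping intervals")
  }
  score <- if ("score" %in% names(x)) {
    as.integer(pmin(1000, pmax(0, round(x$score * 1000))))
  } else if ("n_probes" %in% names(x)) {
    as.integer(x$n_probes)
  } else {
    rep(0L, nrow(x))
  }
  name <- if ("label" %in% names(x)) x$label else rep(".", nrow(x))
  header <- c(
    sprintf("# written by nedomains %s", as.character(utils::packageVersion("nedomains")))
  )
  params <- attr(x, "params")
  if (!is.null(params)) {
    vals <- unlist(params[vapply(params, function(p) is.numeric(p) && length(p) == 1, logical(1))])
    header <- c(header, sprintf("# %s=%s", names(vals), format(vals)))
  }
  if (!is.null(attr(x, "theta"))) {
    header <- c(header, sprintf("# theta=%s", format(attr(x, "theta"))))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(x) > 0) {
    writeLines(
      paste(x$chrom, x$start, x$end, name, score, sep = "\t"),
      con
    )
  }
  invisible(path)
}

#' Read a BED interval set
#'
#' @param path BED file written by [write_intervals()] (or any BED3+).
#' @return Tibble `chrom`, `start`, `end` (+ `label`, `score` if present).
#' @export
read_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      label = character(), score = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  m <- matrix(unlist(lapply(fields, `[`, 1:5)), ncol = 5, byrow = TRUE)
  tibble::tibble(
    chrom = m[, 1],
    start = as.integer(m[, 2]),
    end = as.integer(m[, 3]),
    label = m[, 4],
    score = as.integer(m[, 5])
  )
}

#' Write gene models as BED12
#'
#' @param genes Gene-model tibble with an `exons` list column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  stopifnot_cols(genes, c("gene_id", "chrom", "start", "end", "strand", "exons"), "gene models")
  rows <- purrr::pmap_chr(
    genes[c("gene_id", "chrom", "start", "end", "strand", "exons")],
    function(gene_id, chrom, start, end, strand, exons) {
      exons <- dplyr::arrange(exons, .data$start)
      paste(
        chrom, start, end, gene_id, 0L, strand, start, end, "0",
        nrow(exons),
        paste0(paste(exons$end - exons$start, collapse = ","), ","),
        paste0(paste(exons$start - start, collapse = ","), ","),
        sep = "\t"
      )
    }
  )
  writeLines(rows, path)
  invisible(path)
}

#' Read gene models from BED12
#'
#' @param path BED12 file.
#' @param gene_sets Optional path to a two-column TSV (`gene_id`, `tissue`)
#'   of tissue labels; genes absent from it get tissue `"none"`.
#' @return Gene-model tibble with `exons` list column and `tissue` labels.
#' @export
read_gene_models <- function(path, gene_sets = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 12)) {
    rlang::abort(sprintf("%s: BED12 requires 12 fields per line", path))
  }
  genes <- purrr::map_dfr(fields, function(f) {
    start <- as.integer(f[2])
    sizes <- as.integer(strsplit(f[11], ",")[[1]])
    offs <- as.integer(strsplit(f[12], ",")[[1]])
    ex_start <- start + offs
    ex_end <- ex_start + sizes
    tibble::tibble(
      gene_id = f[4], chrom = f[1], start = start, end = as.integer(f[3]),
      strand = f[6],
      exons = list(tibble::tibble(start = ex_start, end = ex_end))
    )
  })
  genes$tissue <- "none"
  if (!is.null(gene_sets)) {
    sets <- read_gene_sets(gene_sets)
    idx <- match(genes$gene_id, sets$gene_id)
    genes$tissue[!is.na(idx)] <- sets$tissue[idx[!is.na(idx)]]
  }
  genes
}

#' Read / write two-column gene-set tables
#'
#' @param path TSV with header columns `gene_id` and `tissue`.
#' @return Tibble `gene_id`, `tissue`.
#' @export
read_gene_sets <- function(path) {
  sets <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(sets, c("gene_id", "tissue"), "gene sets")
  sets[c("gene_id", "tissue")]
}

#' @rdname read_gene_sets
#' @param genes Gene-model tibble with `gene_id` and `tissue` columns.
#' @export
write_gene_sets <- function(genes, path) {
  readr::write_tsv(genes[c("gene_id", "tissue")], path, progress = FALSE)
  invisible(path)
}

#' Chromosome arm coordinates used for the arm/center partition
#'
#' The fixed arm intervals of the C. elegans chromosomes (assembly ce6 /
#' WS190 coordinates), converted from 1-based inclusive to 0-based
#' half-open. The X chromosome has a single annotated (left) arm.
#'
#' @return Tibble `chrom`, `start`, `end`, `region`.
#' @export
celegans_arms <- function() {
  tibble::tribble(
    ~chrom, ~start, ~end,
    "chrI", 0L, 3745632L,
    "chrI", 10809937L, 15072421L,
    "chrII", 0L, 4708341L,
    "chrII", 11877167L, 15279323L,
    "chrIII", 0L, 3508994L,
    "chrIII", 9947267L, 13783681L,
    "chrIV", 0L, 7317812L,
    "chrIV", 12176624L, 17493785L,
    "chrX", 0L, 4191936L
  ) |> dplyr::mutate(region = "arm")
}
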