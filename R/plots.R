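# ggplot2 views of tracks, calibrations and fits.

#' Plot a probe track with optional domain shading
#'
#' @param track Averaged probe track.
#' @param domains Optional `domain_set` drawn as shaded rectangles.
#' @param chrom Chromosome to show (default: first in the track).
#' @param col Score column.
#' @return A ggplot object.
#' @export
plot_track <- function(track, domains = NULL, chrom = NULL, col = "score") {
  chrom <- chrom %||% track$chrom[1]
  d <- track[track$chrom == chrom, , drop = FALSE]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$start, y = .data[[col]])) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(
      x = sprintf("%s position (bp)", chrom), y = "normalized score",
      title = chrom
    ) +
    ggplot2::theme_minimal()
  if (!is.null(domains)) {
    dd <- domains[domains$chrom == chrom, , drop = FALSE]
    if (nrow(dd) > 0) {
      p <- p + ggplot2::geom_rect(
        data = dd,
        ggplot2::aes(xmin = .data$start, xmax = .data$end),
        ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue",
        inherit.aes = FALSE
      )
    }
  }
  p
}

#' Plot a boundary metaprofile
#'
#' @param profile Tibble from [boundary_metaprofile()].
#' @return A ggplot object.
#' @export
plot_metaprofile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$offset_mid, y = .data$mean_score)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "distance from domain boundary (bp, positive inside)",
      y = "mean secondary score"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot an FDR calibration
#'
#' FDR as a function of the window threshold, with the ceiling and the
#' selected threshold marked.
#'
#' @param object An `fdr_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fdr_calibration
#' @export
autoplot.fdr_calibration <- function(object, ...) {
  tab <- object$table[!is.na(object$table$fdr), , drop = FALSE]
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$theta, y = .data$fdr)) +
    ggplot2::geom_hline(
      yintercept = object$ceiling, linetype = "dashed",
      colour = "firebrick"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "window threshold", y = "empirical FDR") +
    ggplot2::theme_minimal()
  if (!is.na(object$selected_theta)) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$selected_theta,
      linetype = "dotted", colour = "steelblue"
    )
  }
  p
}

#' Autoplot a SAM fit
#'
#' Observed d statistics against their permutation-expected order
#' statistics, with the delta band and significant loci highlighted.
#'
#' @param object A `sam_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sam_fit
#' @export
autoplot.sam_fit <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$dbar, y = .data$d, colour = .data$significant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_abline(
      slope = 1, intercept = c(-object$delta, object$delta),
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "expected d (permutations)", y = "observed d") +
    ggplot2::theme_minimal()
}

#' Autoplot a chromosome occupancy fit
#'
#' @param object An `occupancy_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot occupancy_fit
#' @export
autoplot.occupancy_fit <- function(object, ...) {
  p <- ggplot2::ggplot(
    object$table,
    ggplot2::aes(x = .data$size, y = .data$fraction, shape = .data$autosome)
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "chromosome size (bp)", y = "fraction in domains") +
    ggplot2::theme_minimal()
  if (!is.na(object$slope)) {
    p <- p + ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept,
      colour = "steelblue"
    )
  }
  p
}
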