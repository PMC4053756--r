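# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an FDR calibration
#'
#' @param x An `fdr_calibration` from [calibrate_fdr()].
#' @param ... Unused.
#' @return The threshold/FDR table as a tibble.
#' @method tidy fdr_calibration
#' @export
tidy.fdr_calibration <- function(x, ...) x$table

#' @rdname tidy.fdr_calibration
#' @method glance fdr_calibration
#' @export
glance.fdr_calibration <- function(x, ...) {
  tibble::tibble(
    selected_theta = x$selected_theta,
    default_theta = x$default_theta,
    default_theta_fdr = x$default_theta_fdr,
    default_theta_ok = x$default_theta_ok,
    ceiling = x$ceiling
  )
}

#' Tidy a SAM fit
#'
#' @param x A `sam_fit` from [sam_select()].
#' @param ... Unused.
#' @return Per-locus tibble of d statistics, expected order statistics and
#'   significance calls.
#' @method tidy sam_fit
#' @export
tidy.sam_fit <- function(x, ...) x$table

#' @rdname tidy.sam_fit
#' @method glance sam_fit
#' @export
glance.sam_fit <- function(x, ...) {
  tibble::tibble(
    n_loci = nrow(x$table),
    n_significant = sum(x$table$significant),
    n_up = sum(x$table$direction == "up"),
    n_down = sum(x$table$direction == "down"),
    s0 = x$s0,
    delta = x$delta,
    cutup = x$cutup,
    cutlow = x$cutlow,
    n_perms = x$n_perms
  )
}

#' Tidy a chromosome occupancy fit
#'
#' @param x An `occupancy_fit` from [chromosome_occupancy()].
#' @param ... Unused.
#' @return Per-chromosome tibble of sizes, domain bp and fractions.
#' @method tidy occupancy_fit
#' @export
tidy.occupancy_fit <- function(x, ...) x$table

#' @rdname tidy.occupancy_fit
#' @method glance occupancy_fit
#' @export
glance.occupancy_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r = x$r)
}
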