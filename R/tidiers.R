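#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an orbit calibration fit
#'
#' @param x An `orbit_fit` from [reference_calibration()].
#' @param ... Unused.
#' @return A one-row-per-parameter tibble (`term`, `estimate`).
#' @export
tidy.orbit_fit <- function(x, ...) {
  tibble::tibble(
    term = c("L", "radius", "alpha0", "direction", "center_x", "center_y"),
    estimate = c(x$L, x$radius, x$alpha0, x$direction, x$center[1], x$center[2])
  )
}

#' @rdname tidy.orbit_fit
#' @export
glance.orbit_fit <- function(x, ...) {
  tibble::tibble(L = x$L, alpha0 = x$alpha0, direction = x$direction,
                 residual_rms = x$residual_rms, n_points = nrow(x$points))
}

#' Tidy an orbit self-calibration
#'
#' @param x A `self_calibration` from [self_calibrate_L()].
#' @param ... Unused.
#' @return `tidy()`: the spread-vs-L curve; `glance()`: a one-row summary.
#' @export
tidy.self_calibration <- function(x, ...) x$curve

#' @rdname tidy.self_calibration
#' @export
glance.self_calibration <- function(x, ...) {
  tibble::tibble(L_best = x$L_best,
                 spread_min = min(x$curve$spread_nm, na.rm = TRUE),
                 n_candidates = nrow(x$curve))
}

#' Summaries of an event localization table
#'
#' @param x An `ismflux_events` table from [localize_events()] or
#'   [run_pipeline()].
#' @param ... Unused.
#' @return A one-row tibble with event counts, the acceptance rate, and the
#'   median per-event `sigma`.
#' @export
glance.ismflux_events <- function(x, ...) {
  tibble::tibble(
    n_events = nrow(x),
    n_accepted = sum(x$accepted, na.rm = TRUE),
    n_rejected_sigma = sum(!x$accepted & !x$degenerate, na.rm = TRUE),
    median_sigma = stats::median(x$sigma_nm[!x$degenerate], na.rm = TRUE),
    total_photons = sum(x$total_photons)
  )
}
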