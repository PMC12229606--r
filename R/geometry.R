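#' Detector geometry of the SPAD array
#'
#' Describes the detector array as projected into the sample space. The
#' default is a 5 x 5 array with 150 nm pitch and 100 nm active element size,
#' i.e. the array spans roughly a 600 x 600 nm field of view around the
#' optical axis. Elements are indexed row-major from 0 to
#' `n_rows * n_cols - 1`, so element 12 is the central element of the default
#' array. Hot elements can be excluded from all downstream likelihoods via
#' `excluded_elements`.
#'
#' @param n_rows,n_cols Number of detector rows and columns.
#' @param pitch Element-to-element distance in sample-space nm.
#' @param element_size Side length of the square active area, sample-space nm.
#'   Must not exceed `pitch`.
#' @param excluded_elements Integer vector of row-major element indices
#'   (0-based) to drop from MDFs and counts, e.g. hot pixels.
#' @return An object of class `detector_geometry`.
#' @examples
#' det <- detector_geometry()
#' element_centers(det)
#' @export
detector_geometry <- function(n_rows = 5L, n_cols = 5L, pitch = 150,
                              element_size = 100, excluded_elements = integer()) {
  stopifnot(n_rows >= 1, n_cols >= 1, pitch > 0, element_size > 0)
  if (element_size > pitch) {
    stop("element_size must not exceed pitch (elements cannot overlap)")
  }
  n_el <- as.integer(n_rows) * as.integer(n_cols)
  excluded_elements <- sort(unique(as.integer(excluded_elements)))
  if (length(excluded_elements) &&
      (min(excluded_elements) < 0L || max(excluded_elements) >= n_el)) {
    stop("excluded_elements must be 0-based indices below n_rows * n_cols")
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pitch = pitch, element_size = element_size,
         excluded_elements = excluded_elements),
    class = "detector_geometry"
  )
}

#' Sample-space centers of the detector elements
#'
#' @param det A [detector_geometry()].
#' @param drop_excluded Drop excluded elements from the table?
#' @return A tibble with columns `element` (0-based row-major index), `row`,
#'   `col`, and the element-center coordinates `x_nm`, `y_nm`. The x axis
#'   points along columns, the y axis along rows, origin at the array center.
#' @export
element_centers <- function(det, drop_excluded = FALSE) {
  idx <- seq_len(det$n_rows * det$n_cols) - 1L
  row <- idx %/% det$n_cols
  col <- idx %% det$n_cols
  out <- tibble::tibble(
    element = idx, row = row, col = col,
    x_nm = (col - (det$n_cols - 1) / 2) * det$pitch,
    y_nm = (row - (det$n_rows - 1) / 2) * det$pitch
  )
  if (drop_excluded) out <- out[!out$element %in% det$excluded_elements, ]
  out
}

#' Indices of detector elements used in likelihoods
#'
#' @param det A [detector_geometry()].
#' @return 0-based element indices with excluded elements removed.
#' @export
active_elements <- function(det) {
  setdiff(seq_len(det$n_rows * det$n_cols) - 1L, det$excluded_elements)
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf("<detector_geometry> %d x %d, pitch %g nm, element %g nm",
              x$n_rows, x$n_cols, x$pitch, x$element_size))
  if (length(x$excluded_elements)) {
    cat(sprintf(", excluded: %s", paste(x$excluded_elements, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Orbit geometry of the targeted coordinate pattern
#'
#' The beam is steered along `n_positions` points on a circle of diameter `L`
#' (the targeted coordinate pattern, TCP). Position `i` (0-based) sits at the
#' offset `delta_i = (L/2) * (cos(theta_i), sin(theta_i))` with
#' `theta_i = alpha0 + direction * 2 * pi * i / n_positions`.
#'
#' @param L Orbit (TCP) diameter in nm.
#' @param alpha0 Start phase in radians.
#' @param direction Rotation direction, `+1` (counter-clockwise) or `-1`.
#' @param n_positions Number of probed positions per orbit (>= 3, except for
#'   the degenerate single-position orbit used internally for static-beam
#'   localization, which uses `L = 0`).
#' @param period_ms Orbit period in ms; the dwell per angular position is
#'   `period_ms / n_positions`.
#' @return An object of class `orbit_geometry`.
#' @examples
#' orb <- orbit_geometry(L = 90)
#' orbit_offsets(orb)
#' @export
orbit_geometry <- function(L = 90, alpha0 = 0, direction = 1L,
                           n_positions = 32L, period_ms = 1.92) {
  stopifnot(L >= 0, period_ms > 0)
  if (!direction %in% c(-1, 1)) stop("direction must be +1 or -1")
  n_positions <- as.integer(n_positions)
  if (n_positions < 1L) stop("n_positions must be >= 1")
  if (L > 0 && n_positions < 3L) stop("an orbit with L > 0 needs n_positions >= 3")
  structure(
    list(L = L, alpha0 = alpha0, direction = as.integer(direction),
         n_positions = n_positions, period_ms = period_ms),
    class = "orbit_geometry"
  )
}

#' Beam offsets of the orbit positions
#'
#' @param orbit An [orbit_geometry()].
#' @return A tibble with columns `position` (0-based), `theta_rad`, `dx_nm`,
#'   `dy_nm`.
#' @export
orbit_offsets <- function(orbit) {
  if (!is.null(orbit$explicit_offsets)) {
    off <- orbit$explicit_offsets
    off$position <- seq_len(nrow(off)) - 1L
    return(off)
  }
  i <- seq_len(orbit$n_positions) - 1L
  theta <- orbit$alpha0 + orbit$direction * 2 * pi * i / orbit$n_positions
  tibble::tibble(
    position = i, theta_rad = theta,
    dx_nm = (orbit$L / 2) * cos(theta),
    dy_nm = (orbit$L / 2) * sin(theta)
  )
}

#' @export
print.orbit_geometry <- function(x, ...) {
  cat(sprintf(
    "<orbit_geometry> L = %g nm, %d positions, alpha0 = %g rad, dir %+d, %g ms/orbit\n",
    x$L, x$n_positions, x$alpha0, x$direction, x$period_ms))
  invisible(x)
}

#' Parametric optical model for the MDF simulation
#'
#' A closed-form scalar stand-in for the focused fields of the instrument:
#' the excitation profile is the parametric doughnut
#' `Exc(rho) = (rho^2 / w^2) * exp(-2 * rho^2 / w^2)` (exactly zero at its
#' center, radially symmetric, maximum at `rho = w / sqrt(2)`), and the
#' detection PSF is an isotropic 2D Gaussian with standard deviation
#' `sigma_det`, integrated over each element's square active area. By default
#' `w = 0.61 * lambda_exc / NA` (so the doughnut width matches a vortex focus
#' at the stated wavelength and aperture) and
#' `sigma_det = 0.21 * lambda_em / NA`.
#'
#' @param wavelength_exc Excitation wavelength, nm.
#' @param wavelength_em Emission wavelength, nm.
#' @param numerical_aperture Objective NA.
#' @param refractive_index Immersion refractive index (kept for provenance;
#'   the scalar model does not use it).
#' @param doughnut_waist Doughnut waist parameter `w` in nm; default derived
#'   from wavelength and NA.
#' @param detection_sigma Detection PSF standard deviation in nm; default
#'   derived from wavelength and NA.
#' @return An object of class `optics_model`.
#' @export
optics_model <- function(wavelength_exc = 635, wavelength_em = 660,
                         numerical_aperture = 1.4, refractive_index = 1.5,
                         doughnut_waist = NULL, detection_sigma = NULL) {
  stopifnot(wavelength_exc > 0, wavelength_em > 0,
            numerical_aperture > 0, refractive_index > 0)
  if (is.null(doughnut_waist)) {
    doughnut_waist <- 0.61 * wavelength_exc / numerical_aperture
  }
  if (is.null(detection_sigma)) {
    detection_sigma <- 0.21 * wavelength_em / numerical_aperture
  }
  stopifnot(doughnut_waist > 0, detection_sigma > 0)
  structure(
    list(wavelength_exc = wavelength_exc, wavelength_em = wavelength_em,
         numerical_aperture = numerical_aperture,
         refractive_index = refractive_index,
         doughnut_waist = doughnut_waist, detection_sigma = detection_sigma),
    class = "optics_model"
  )
}

#' @export
print.optics_model <- function(x, ...) {
  cat(sprintf(
    "<optics_model> exc %g nm / em %g nm, NA %g, w = %.1f nm, sigma_det = %.1f nm\n",
    x$wavelength_exc, x$wavelength_em, x$numerical_aperture,
    x$doughnut_waist, x$detection_sigma))
  invisible(x)
}

#' Doughnut excitation intensity profile
#'
#' `(rho^2 / w^2) * exp(-2 * rho^2 / w^2)`: zero at the center, maximal on the
#' ring `rho = w / sqrt(2)`.
#'
#' @param rho Radial distance(s) from the beam center, nm.
#' @param optics An [optics_model()].
#' @return Intensity values (arbitrary units, max `exp(-1)/2`).
#' @export
doughnut_profile <- function(rho, optics) {
  w2 <- optics$doughnut_waist^2
  (rho^2 / w2) * exp(-2 * rho^2 / w2)
}
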