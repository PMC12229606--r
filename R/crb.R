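# Fisher information of the multinomial photon model, vectorized over
# positions. Gradients of p_ij by central finite differences (step in nm).
.fisher_batch <- function(mdf, bkg, x, y, n_photons, step) {
  np <- length(x)
  pts_x <- c(x + step, x - step, x, x, x)
  pts_y <- c(y, y, y + step, y - step, y)
  p <- detection_probabilities(mdf, bkg, pts_x, pts_y)
  ix <- function(k) ((k - 1) * np + 1):(k * np)
  dpx <- (p[ix(1), , drop = FALSE] - p[ix(2), , drop = FALSE]) / (2 * step)
  dpy <- (p[ix(3), , drop = FALSE] - p[ix(4), , drop = FALSE]) / (2 * step)
  p0 <- p[ix(5), , drop = FALSE]
  list(
    fxx = n_photons * rowSums(dpx^2 / p0),
    fxy = n_photons * rowSums(dpx * dpy / p0),
    fyy = n_photons * rowSums(dpy^2 / p0)
  )
}

#' Fisher information matrix of the photon-count model
#'
#' For `N` photons distributed multinomially over the detection
#' probabilities, `F = N * sum_ij (grad p_ij)(grad p_ij)^T / p_ij`.
#' Gradients are taken by central finite differences on the interpolated
#' probabilities.
#'
#' @param mdf An `mdf_set`.
#' @param bkg A [background_model()] or SBR value.
#' @param x,y Emitter position (nm, scalars). Must be at least one
#'   finite-difference step inside the grid.
#' @param n_photons Total photon count `N` the matrix assumes.
#' @param step Finite-difference step in nm; default one MDF pixel.
#' @return A symmetric positive-semidefinite 2x2 matrix.
#' @export
fisher_information <- function(mdf, bkg, x, y, n_photons = 100,
                               step = mdf$base$grid$pixel_size) {
  f <- .fisher_batch(mdf, bkg, x, y, n_photons, step)
  matrix(c(f$fxx, f$fxy, f$fxy, f$fyy), 2, 2)
}

#' Cramer-Rao bound on the localization uncertainty
#'
#' The scalar bound is the rms of the two per-axis bounds,
#' `sigma_CRB = sqrt(tr(F^-1) / 2)`, matching the
#' `sigma = sqrt((sigma_x^2 + sigma_y^2) / 2)` convention used for measured
#' localization spreads. A singular information matrix yields `Inf`.
#'
#' @inheritParams fisher_information
#' @return The bound in nm (vectorized over positions).
#' @examples
#' base <- simulate_base_mdf(grid = mdf_grid(2.5, 400))
#' mdf <- expand_orbit(base, orbit_geometry(L = 90))
#' sigma_crb(mdf, 10, 0, 0, n_photons = 100)
#' @export
sigma_crb <- function(mdf, bkg, x, y, n_photons = 100,
                      step = mdf$base$grid$pixel_size) {
  f <- .fisher_batch(mdf, bkg, x, y, n_photons, step)
  det_f <- f$fxx * f$fyy - f$fxy^2
  out <- sqrt((f$fxx + f$fyy) / (2 * det_f))
  out[det_f <= 0] <- Inf
  out
}

#' Map of the Cramer-Rao bound over the field of view
#'
#' Evaluates the bound on a decimated grid. For the single-element reduction
#' the map develops very large values around the orbit circle and near the
#' doughnut-maximum ring; for the full array it stays finite across the
#' detector field of view.
#'
#' @param mdf An `mdf_set`.
#' @param bkg A [background_model()] or SBR value.
#' @param n_photons Reference photon count of the map.
#' @param decimation Evaluate every `decimation`-th MDF pixel.
#' @param fov_radius Restrict to points with `sqrt(x^2+y^2) <= fov_radius`
#'   (nm). Default: the detector footprint (clipped to the usable grid).
#' @return A tibble of class `crb_map` with columns `x_nm`, `y_nm`,
#'   `var_x`, `var_y` (inverse-Fisher diagonal, nm^2), `sigma_crb` (nm), and
#'   attributes `n_ref`, `sbr`.
#' @export
crb_map <- function(mdf, bkg, n_photons = 100, decimation = 8L,
                    fov_radius = NULL) {
  g <- mdf$base$grid
  sp <- .search_spec(mdf, NULL)
  half <- sp$x_range[2] - g$pixel_size
  if (is.null(fov_radius)) fov_radius <- half
  ax <- g$axis[seq(1, g$n, by = decimation)]
  ax <- ax[abs(ax) <= min(fov_radius, half)]
  pts <- expand.grid(x_nm = ax, y_nm = ax)
  pts <- pts[pts$x_nm^2 + pts$y_nm^2 <= fov_radius^2, ]
  f <- .fisher_batch(mdf, bkg, pts$x_nm, pts$y_nm, n_photons, g$pixel_size)
  det_f <- f$fxx * f$fyy - f$fxy^2
  var_x <- ifelse(det_f > 0, f$fyy / det_f, Inf)
  var_y <- ifelse(det_f > 0, f$fxx / det_f, Inf)
  out <- tibble::new_tibble(
    tibble::tibble(x_nm = pts$x_nm, y_nm = pts$y_nm,
                   var_x = var_x, var_y = var_y,
                   sigma_crb = sqrt((var_x + var_y) / 2)),
    class = "crb_map"
  )
  attr(out, "n_ref") <- n_photons
  attr(out, "sbr") <- .as_sbr(bkg)
  out
}

#' Average bound within a circular field of view
#'
#' Arithmetic mean of `sigma_crb` over all map points inside the centered
#' disk of the given diameter. A zero diameter returns the value at (or
#' nearest to) the pattern center.
#'
#' @param map A [crb_map()].
#' @param fov_diameter Disk diameter in nm.
#' @return Mean bound in nm.
#' @export
crb_fov_average <- function(map, fov_diameter) {
  stopifnot(fov_diameter >= 0)
  r2 <- map$x_nm^2 + map$y_nm^2
  inside <- r2 <= (fov_diameter / 2)^2
  if (!any(inside)) inside <- r2 == min(r2)
  mean(map$sigma_crb[inside])
}

#' Expected photon count map under constant illumination power
#'
#' With laser power, TCP position and L held constant, the expected photon
#' count per localization depends on the emitter position through the sum of
#' all MDFs. The map is rescaled so the count equals `n_center` at the
#' pattern center.
#'
#' @param mdf An `mdf_set`.
#' @param x,y Positions (nm).
#' @param n_center Photon count at the TCP center.
#' @return Expected counts `N(x, y)`.
#' @export
expected_photon_map <- function(mdf, x, y, n_center = 100) {
  s0 <- sum(mdf_probe(mdf, 0, 0))
  n_center * rowSums(mdf_probe(mdf, x, y)) / s0
}

#' Effective localization uncertainty map
#'
#' Scales the constant-N bound by the position-dependent expected photon
#' count: `sigma_eff(x, y) = sigma_crb(x, y; N_ref) * sqrt(N_ref / N(x, y))`
#' with `N(x, y)` from [expected_photon_map()] normalized to `n_center` at
#' the center. This is the uncertainty actually attainable when acquisition
#' time, not photon number, is held constant.
#'
#' @inheritParams crb_map
#' @param n_center Expected photons for an emitter at the TCP center.
#' @return A `crb_map` tibble with extra columns `n_expected` and
#'   `sigma_eff` (nm).
#' @export
effective_uncertainty_map <- function(mdf, bkg, n_center = 100,
                                      decimation = 8L, fov_radius = NULL) {
  stopifnot(n_center > 0)
  map <- crb_map(mdf, bkg, n_photons = n_center, decimation = decimation,
                 fov_radius = fov_radius)
  n_xy <- expected_photon_map(mdf, map$x_nm, map$y_nm, n_center)
  map$n_expected <- n_xy
  map$sigma_eff <- ifelse(n_xy > 0, map$sigma_crb * sqrt(n_center / n_xy), Inf)
  map
}

#' @export
print.crb_map <- function(x, ...) {
  cat(sprintf("<crb_map> %d points, N_ref = %g, SBR = %g, sigma range [%.2f, %.2f] nm\n",
              nrow(x), attr(x, "n_ref"), attr(x, "sbr"),
              min(x$sigma_crb), max(x$sigma_crb[is.finite(x$sigma_crb)])))
  NextMethod()
}
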