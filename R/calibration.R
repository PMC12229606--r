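#' Least-squares circle fit
#'
#' Algebraic (Kasa) least-squares fit followed by one Gauss-Newton geometric
#' refinement step. Deterministic.
#'
#' @param x,y Point coordinates.
#' @return A list with `center` (length-2), `radius`, `residual_rms`.
#' @export
fit_circle <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  if (qr(A)$rank < 3) stop("rank-deficient circle fit (collinear points?)")
  sol <- qr.solve(A, b)
  cx <- sol[1]; cy <- sol[2]
  r <- sqrt(sol[3] + cx^2 + cy^2)
  # one geometric Gauss-Newton step on (cx, cy, r)
  for (it in 1) {
    di <- sqrt((x - cx)^2 + (y - cy)^2)
    if (any(di == 0)) break
    J <- cbind(-(x - cx) / di, -(y - cy) / di, -1)
    res <- di - r
    step <- tryCatch(qr.solve(J, -res), error = function(e) c(0, 0, 0))
    cx <- cx + step[1]; cy <- cy + step[2]; r <- r + step[3]
  }
  di <- sqrt((x - cx)^2 + (y - cy)^2)
  list(center = c(cx, cy), radius = r,
       residual_rms = sqrt(mean((di - r)^2)))
}

#' Orbit calibration from a reference (bead) measurement
#'
#' With the beam orbiting around a bright, fixed scatterer and the detector
#' in descanned mode, the apparent particle position traces the orbit:
#' localizing the particle for each angular position against the unshifted
#' base MDF yields a circle of `N_c` points, from which the actual orbit
#' radius, start phase and rotation direction are fitted. Because the
#' descanned image moves opposite to the beam, the beam offset at position
#' `i` is `delta_i = center - r'_i`, where `r'_i` is the per-angle
#' localization.
#'
#' @param tensor A `count_tensor` of the reference measurement (high photon
#'   counts per angle).
#' @param base An `mdf_base` (the unshifted `I_0j` stack).
#' @param bkg A [background_model()] or SBR value.
#' @param orbits_per_block Orbits summed per per-angle localization block.
#' @param search As in [localize_mle()]; by default the per-angle
#'   localizations refine to a quarter MDF pixel, since the circle fit
#'   benefits from sub-pixel resolution.
#' @return A list of class `orbit_fit`: `radius`, `L`, `alpha0`,
#'   `direction`, `center`, `residual_rms`, and the per-angle points in
#'   `points`.
#' @export
reference_calibration <- function(tensor, base, bkg, orbits_per_block = 100L,
                                  search = NULL) {
  stopifnot(inherits(tensor, "count_tensor"), inherits(base, "mdf_base"))
  if (is.null(search)) {
    search <- list(n_refine = 6L, min_step = base$grid$pixel_size / 4)
  }
  d <- dim(tensor$counts)
  n_blocks <- max(1L, d[1] %/% orbits_per_block)
  nc <- d[2]
  # a static-beam MDF set: single orbit position at zero offset
  static <- expand_orbit(base, orbit_geometry(L = 0, n_positions = 1L,
                                              period_ms = tensor$orbit$period_ms))
  pts <- list()
  for (b in seq_len(n_blocks)) {
    orbs <- ((b - 1L) * orbits_per_block + 1L):min(b * orbits_per_block, d[1])
    for (i in seq_len(nc)) {
      nj <- apply(tensor$counts[orbs, i, , drop = FALSE], 3, sum)
      if (sum(nj) < 1) next
      loc <- localize_mle(matrix(nj, nrow = 1), static, bkg, search)
      pts[[length(pts) + 1L]] <- tibble::tibble(
        block = b, position = i - 1L, x_nm = loc$x_nm, y_nm = loc$y_nm)
    }
  }
  pts <- dplyr::bind_rows(pts)
  fit <- fit_circle(pts$x_nm, pts$y_nm)
  # beam offsets are opposite to the apparent particle displacement
  phi <- atan2(fit$center[2] - pts$y_nm, fit$center[1] - pts$x_nm)
  alpha0 <- atan2(mean(sin(phi[pts$position == 0L])),
                  mean(cos(phi[pts$position == 0L])))
  # direction: sign of the mean wrapped phase increment along the orbit
  ord <- pts[order(pts$block, pts$position), ]
  phi_ord <- atan2(fit$center[2] - ord$y_nm, fit$center[1] - ord$x_nm)
  dphi <- diff(phi_ord)
  dphi <- atan2(sin(dphi), cos(dphi))  # wrap to (-pi, pi]
  keep <- diff(ord$position) == 1L     # within-block consecutive steps only
  direction <- if (mean(dphi[keep]) >= 0) 1L else -1L
  structure(
    list(radius = fit$radius, L = 2 * fit$radius, alpha0 = alpha0,
         direction = direction, center = fit$center,
         residual_rms = fit$residual_rms, points = pts),
    class = "orbit_fit"
  )
}

#' @export
print.orbit_fit <- function(x, ...) {
  cat(sprintf(
    "<orbit_fit> L = %.2f nm (radius %.2f), alpha0 = %.4f rad, dir %+d, rms %.2f nm\n",
    x$L, x$radius, x$alpha0, x$direction, x$residual_rms))
  invisible(x)
}

#' Orbit-diameter self-calibration from single-molecule data
#'
#' Exploits the descanned shift of the molecule image with the orbit angle:
#' the event is localized separately in 4 quadrants of consecutive orbit
#' positions under each candidate orbit diameter `L`. When the assumed `L`
#' is wrong, the quadrant localizations spread apart systematically; the
#' best `L` minimizes the rms distance of the 4 quadrant positions from
#' their centroid.
#'
#' @param event An `N_c x N_d` event matrix (pool several events for a
#'   deeper minimum).
#' @param base An `mdf_base`.
#' @param orbit The nominal [orbit_geometry()] (provides phase, direction,
#'   `N_c`); its `L` is replaced by each candidate.
#' @param bkg A [background_model()] or SBR value.
#' @param candidates Candidate `L` values in nm.
#' @param search As in [localize_mle()].
#' @return A list of class `self_calibration`: `L_best`, and `curve`, a
#'   tibble of (`L`, `spread_nm`, `n_quadrants`).
#' @export
self_calibrate_L <- function(event, base, orbit, bkg,
                             candidates = seq(60, 120, by = 2),
                             search = NULL) {
  stopifnot(inherits(base, "mdf_base"))
  rows <- purrr::map(candidates, function(L) {
    mdf_l <- expand_orbit(base, orbit_geometry(L, orbit$alpha0,
                                               orbit$direction,
                                               orbit$n_positions,
                                               orbit$period_ms))
    q <- localize_per_subset(event, mdf_l, bkg, search = search)
    q <- q[!q$skipped & !q$on_border, ]
    if (nrow(q) < 2) {
      return(tibble::tibble(L = L, spread_nm = NA_real_, n_quadrants = nrow(q)))
    }
    spread <- sqrt(mean((q$x_nm - mean(q$x_nm))^2 + (q$y_nm - mean(q$y_nm))^2))
    tibble::tibble(L = L, spread_nm = spread, n_quadrants = nrow(q))
  })
  curve <- dplyr::bind_rows(rows)
  if (all(is.na(curve$spread_nm))) {
    stop("all candidate L values gave degenerate quadrant localizations")
  }
  structure(
    list(L_best = curve$L[which.min(curve$spread_nm)], curve = curve),
    class = "self_calibration"
  )
}

#' @export
print.self_calibration <- function(x, ...) {
  cat(sprintf("<self_calibration> L_best = %g nm (from %d candidates)\n",
              x$L_best, nrow(x$curve)))
  invisible(x)
}
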