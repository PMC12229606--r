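# Shared fixtures, built once per test run.
#
# The shared grid is 480 px at 2.5 nm (+/- 600 nm): large enough to hold the
# detector footprint (+/-350 nm), the orbit shift and the finite-difference
# stencils, small enough to keep the suite fast.

tg_grid <- mdf_grid(pixel_size = 2.5, n_pixels = 480)
tg_det <- detector_geometry()
tg_optics <- optics_model()
tg_base <- simulate_base_mdf(tg_optics, tg_det, tg_grid)
tg_orbit <- orbit_geometry(L = 90)
tg_mdf <- expand_orbit(tg_base, tg_orbit)
tg_single <- reduce_to_single_element(tg_mdf)

# Draw a Poisson event matrix with expected total N at a given position.
draw_event <- function(mdf, x, y, n_photons, sbr = 10) {
  p <- detection_probabilities(mdf, sbr, x, y)
  dims <- mdf_dims(mdf)
  matrix(stats::rpois(length(p), n_photons * p),
         nrow = dims[["n_positions"]], byrow = TRUE)
}

# Tiny toy MDF on a coarse grid, for exhaustive-search oracles: 2 detector
# elements, 3 orbit positions, smooth positive maps.
toy_mdf <- local({
  g <- mdf_grid(pixel_size = 10, n_pixels = 16)
  det <- detector_geometry(n_rows = 1L, n_cols = 2L, pitch = 60,
                           element_size = 50)
  maps <- array(0, c(g$n, g$n, 2))
  for (j in 1:2) {
    cx <- c(-30, 30)[j]
    maps[, , j] <- outer(g$axis, g$axis, function(x, y) {
      exp(-((x - cx)^2 + y^2) / (2 * 60^2))
    })
  }
  base <- as_mdf_base(maps, g, det)
  expand_orbit(base, orbit_geometry(L = 40, n_positions = 3L))
})

rms2d <- function(x, y) sqrt((stats::var(x) + stats::var(y)) / 2)
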