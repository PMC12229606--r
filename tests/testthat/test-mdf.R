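test_that("simulated base MDFs respect the doughnut and detector symmetries", {
  base <- tg_base
  g <- tg_grid
  # excitation zero at the beam center: the total detection value there is
  # interpolation-limited (no pixel center sits exactly at the origin) and
  # orders of magnitude below the normalized peak of 1
  static <- expand_orbit(base, orbit_geometry(L = 0, n_positions = 1))
  expect_lt(sum(mdf_probe(static, 0, 0)), 5e-4)
  expect_identical(doughnut_profile(0, tg_optics), 0)
  # mirror symmetry: maps for elements 11 and 13 are x-mirror images
  m11 <- matrix(base$values[, 12], g$n, g$n)
  m13 <- matrix(base$values[, 14], g$n, g$n)
  expect_equal(m11, m13[g$n:1, ], tolerance = 1e-12)
  # normalization: total detection probability is 1 at the doughnut maximum
  w <- tg_optics$doughnut_waist
  expect_equal(sum(mdf_probe(static, w / sqrt(2), 0)), 1, tolerance = 1e-9)
  expect_true(all(base$values >= 0))
})

test_that("grid and parameter validation errors fire", {
  expect_error(simulate_base_mdf(grid = mdf_grid(2.5, 100)), "footprint")
  expect_error(expand_orbit(tg_base, orbit_geometry(L = 2400)), "margin")
  expect_error(mdf_probe(tg_mdf, 1e4, 0), "outside")
})

test_that("orbit expansion translates the base maps", {
  # L = 0: every orbit position reproduces the base exactly
  mdf0 <- expand_orbit(tg_base, orbit_geometry(L = 0, n_positions = 4))
  m <- mdf_probe(mdf0, 33, -71)
  m_mat <- matrix(m, nrow = 4, byrow = TRUE)
  for (i in 2:4) expect_equal(m_mat[i, ], m_mat[1, ])

  # integer-pixel shift: page equals the index-shifted base array exactly
  px <- tg_grid$pixel_size
  orb <- orbit_geometry(L = 2 * 8 * px, alpha0 = 0, n_positions = 4)  # delta_0 = 8 px
  mdf_int <- expand_orbit(tg_base, orb)
  page <- mdf_page(mdf_int, position = 0, element = 12)
  base_map <- matrix(tg_base$values[, 13], tg_grid$n, tg_grid$n)
  shifted <- matrix(0, tg_grid$n, tg_grid$n)
  shifted[9:tg_grid$n, ] <- base_map[1:(tg_grid$n - 8), ]
  expect_equal(page, shifted, tolerance = 1e-12)

  # subpixel translation consistency at probe level
  off <- orbit_offsets(tg_orbit)
  pt <- c(12.25, -40.5)
  m_all <- mdf_probe(tg_mdf, pt[1], pt[2])
  m_mat <- matrix(m_all, nrow = 32, byrow = TRUE)
  static <- expand_orbit(tg_base, orbit_geometry(L = 0, n_positions = 1))
  for (i in c(1, 9, 20)) {
    direct <- mdf_probe(static, pt[1] - off$dx_nm[i], pt[2] - off$dy_nm[i])
    expect_equal(m_mat[i, ], as.vector(direct), tolerance = 1e-12)
  }
})

test_that("single-element reduction conserves probability and is idempotent", {
  red <- tg_single
  expect_equal(unname(mdf_dims(red)["n_elements"]), 1L)
  pts <- cbind(c(0, 80, -150), c(0, 40, 200))
  m_full <- mdf_probe(tg_mdf, pts[, 1], pts[, 2])
  m_red <- mdf_probe(red, pts[, 1], pts[, 2])
  for (k in 1:3) {
    full_by_pos <- rowSums(matrix(m_full[k, ], nrow = 32, byrow = TRUE))
    expect_equal(full_by_pos, m_red[k, ], tolerance = 1e-12)
  }
  expect_identical(reduce_to_single_element(red), red)
})

test_that("excluded hot elements are dropped from probe output", {
  det2 <- detector_geometry(excluded_elements = c(3, 17))
  base2 <- tg_base
  base2$det <- det2
  mdf2 <- expand_orbit(base2, tg_orbit)
  expect_equal(unname(mdf_dims(mdf2)["n_elements"]), 23L)
  m_full <- matrix(mdf_probe(tg_mdf, 50, 50), nrow = 32, byrow = TRUE)
  m_excl <- matrix(mdf_probe(mdf2, 50, 50), nrow = 32, byrow = TRUE)
  expect_equal(m_excl, m_full[, -c(4, 18)], tolerance = 1e-14)
})

test_that("measured-MDF preparation rescales, smooths, and normalizes", {
  g <- mdf_grid(pixel_size = 4, n_pixels = 200)
  det <- detector_geometry(n_rows = 1, n_cols = 1, pitch = 100, element_size = 100)
  orb <- orbit_geometry(L = 60, n_positions = 8)
  # synthetic disc image
  disc <- outer(g$axis, g$axis, function(x, y) as.numeric(x^2 + y^2 < 150^2))
  stack <- array(disc, c(g$n, g$n, 1))

  # identity transform: output base proportional to input
  mdf_id <- prepare_measured_mdf(stack, g, det, orb, x_rescale = 1,
                                 smoothing = NULL)
  ratio <- mdf_id$base$values[disc > 0, 1] / disc[disc > 0]
  expect_equal(diff(range(ratio)), 0, tolerance = 1e-12)
  expect_equal(mdf_id$provenance, "measured")

  # x_rescale = 0.8 shrinks the blob aspect ratio to ~0.8 (moment analysis)
  mdf_sq <- prepare_measured_mdf(stack, g, det, orb, x_rescale = 0.8,
                                 smoothing = NULL)
  img <- matrix(mdf_sq$base$values[, 1], g$n, g$n)
  wx <- sqrt(sum(img * outer(g$axis^2, rep(1, g$n))) / sum(img))
  wy <- sqrt(sum(img * outer(rep(1, g$n), g$axis^2)) / sum(img))
  expect_equal(wx / wy, 0.8, tolerance = 0.03)

  # smoothing a delta image: peak strictly decreases, mass conserved
  skip_if_not_installed("EBImage")
  delta <- array(0, c(g$n, g$n, 1))
  delta[100, 100, 1] <- 1
  mdf_sm <- prepare_measured_mdf(delta, g, det, orb, x_rescale = 1,
                                 smoothing = list(uniform_px = 5, gaussian_px = 2))
  # peak is spread over many pixels after smoothing
  expect_lt(max(mdf_sm$base$values[, 1]) / sum(mdf_sm$base$values[, 1]), 0.5)
  # blur conserves mass and strictly lowers the peak (checked unnormalized)
  img0 <- matrix(0, g$n, g$n); img0[100, 100] <- 1
  box <- matrix(1 / 25, 5, 5)
  sm2 <- EBImage::gblur(EBImage::filter2(img0, box, boundary = "replicate"),
                        sigma = 2, boundary = "replicate")
  expect_equal(sum(sm2), 1, tolerance = 1e-6)
  expect_lt(max(sm2), 1)

  # shape mismatch errors
  expect_error(prepare_measured_mdf(array(0, c(10, 10, 1)), g, det, orb),
               "dimensions")
})

test_that("MDF sets round-trip through TIFF + JSON", {
  g <- mdf_grid(pixel_size = 5, n_pixels = 150)
  det <- detector_geometry(excluded_elements = 7L)
  base <- simulate_base_mdf(tg_optics, det, g)
  mdf <- expand_orbit(base, orbit_geometry(L = 70, alpha0 = 0.3))
  path <- file.path(withr::local_tempdir(), "mdf")
  write_mdf(mdf, path)
  back <- read_mdf(path)
  expect_equal(back$orbit$L, 70)
  expect_equal(back$orbit$alpha0, 0.3)
  expect_equal(back$base$det$excluded_elements, 7L)
  expect_equal(back$provenance, "simulated")
  m1 <- mdf_probe(mdf, 40, -60)
  m2 <- mdf_probe(back, 40, -60)
  expect_equal(m2, m1, tolerance = 1e-6)
})
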