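test_that("traces sum tensors and respect element exclusions", {
  scr <- step_pattern("steps", step = 20, n_steps = 2, dwell_ms = 9.6)
  tens <- simulate_trace(tg_mdf, scr, rate = 100, bkg_rate = 10, n_orbits = 10,
                         seed = 12)
  tr <- trace_from_tensor(tens)
  expect_equal(tr$photons, apply(tens$counts, 1, sum))
  # excluding elements removes exactly their contribution
  tr_ex <- trace_from_tensor(tens, excluded_elements = c(0, 4))
  removed <- apply(tens$counts[, , c(1, 5)], 1, sum)
  expect_equal(tr_ex$photons, tr$photons - removed)
  # all-zero tensor gives an all-zero trace
  t0 <- simulate_trace(tg_mdf, scr, rate = 0, bkg_rate = 0, n_orbits = 5,
                       seed = 1)
  expect_true(all(trace_from_tensor(t0)$photons == 0))
})

test_that("two-Gaussian threshold fitting finds the background mode", {
  set.seed(41)
  trace <- c(rpois(3000, 20), rpois(600, 200))[sample(3600)]
  thr <- fit_threshold(trace)
  expect_gt(thr, 18)
  expect_lt(thr, 22)
  # binning invariance: halving the bin count moves the threshold < 10%
  thr2 <- fit_threshold(trace, bins = 30)
  expect_lt(abs(thr2 - thr) / thr, 0.10)
  # the valley method lands between the modes
  thr_v <- fit_threshold(trace, method = "valley")
  expect_gt(thr_v, thr)
  expect_lt(thr_v, 200)
  # manual override passes through
  expect_identical(fit_threshold(trace, manual = 33), 33)
  # unimodal trace errors with a diagnostic
  expect_error(fit_threshold(rpois(2000, 50)), "threshold")
})

test_that("event segmentation returns maximal above-threshold runs", {
  ev <- segment_events(c(0, 0, 5, 6, 0, 7, 0), 1)
  expect_equal(ev$start, c(2L, 5L))
  expect_equal(ev$end, c(4L, 6L))
  expect_equal(nrow(segment_events(c(1, 2, 3), 10)), 0)
  # threshold is strict: values equal to it stay outside
  expect_equal(nrow(segment_events(c(2, 2, 2), 2)), 0)
  # run covering the trace end closes properly
  ev2 <- segment_events(c(0, 9, 9), 1)
  expect_equal(c(ev2$start, ev2$end), c(1L, 3L))
})

test_that("filters enforce photons, duration and Poisson-fluctuation limits", {
  cfg <- filter_config()
  # boundary cases via a hand-built trace
  trace <- c(0, rep(400, 5), 0, rep(399, 4), 0, rep(500, 4), 0)
  ev <- segment_events(trace, 100)
  ev <- apply_filters(ev, trace, cfg)
  expect_equal(ev$total_photons, c(2000, 1596, 2000))
  expect_true(ev$pass_photons[1])   # exactly at the threshold passes
  expect_false(ev$pass_photons[2])  # 1596 < 2000 rejected
  expect_true(ev$pass_duration[1])  # 5 orbits passes
  expect_false(ev$pass_duration[3]) # 4 orbits rejected
  # monotonicity: stricter thresholds never accept more events
  stricter <- apply_filters(ev[1:3, 1:3], trace,
                            filter_config(min_photons = 3000, min_orbits = 6))
  expect_lte(sum(stricter$pass_all), sum(ev$pass_all))
})

test_that("the variance filter rarely rejects true constant-rate events", {
  set.seed(55)
  n_ev <- 1000
  sds <- replicate(n_ev, {
    seg <- rpois(20, 400)
    sd(seg) / sqrt(mean(seg))
  })
  expect_lt(mean(sds > 2.5), 0.02)
})

test_that("three-segment sigma follows the population-sd convention", {
  # segment positions (0,0), (3,0), (6,0): sd_x = 3, sd_y = 0, sigma = sqrt(4.5)
  xs <- c(0, 3, 6); ys <- c(0, 0, 0)
  expect_equal(sqrt(0.5 * (var(xs) + var(ys))), sqrt(4.5), tolerance = 1e-12)
  expect_equal(sqrt(4.5), 2.121, tolerance = 1e-3)
  # equal-split with remainder: the last segment absorbs it
  b <- ismflux:::.segment_bounds(0L, 17L)
  expect_equal(unname(b[, "end"] - b[, "start"]), c(5, 5, 7))
  expect_equal(unname(b[1, "start"]), 0)
  expect_equal(unname(b[3, "end"]), 17)
})

test_that("event localization pipeline recovers a blinking emitter", {
  # one emitter at a fixed position, strong events over a quiet background
  sites <- data.frame(x_nm = 80, y_nm = -40)
  scr <- nanoruler_script(sites, on_ms = 150, off_ms = 350,
                          duration_ms = 8000, seed = 23)
  tens <- simulate_trace(tg_mdf, scr, rate = 30, bkg_rate = 10,
                         n_orbits = as.integer(8000 / 1.92), seed = 24)
  cfg <- filter_config(min_photons = 500, min_orbits = 5,
                       poisson_factor = 2.5, sigma_threshold = 10)
  res <- run_pipeline(tens, tg_mdf, bkg = 3, cfg = cfg)
  acc <- res[res$accepted, ]
  expect_gt(nrow(acc), 2)
  expect_lt(abs(mean(acc$x_nm) - 80), 5)
  expect_lt(abs(mean(acc$y_nm) + 40), 5)
  expect_true(all(res$sigma_nm[res$accepted] < 10))
  # determinism: the same tensor and config reproduce the same records
  res2 <- run_pipeline(tens, tg_mdf, bkg = 3, cfg = cfg)
  expect_equal(res2$x_nm, res$x_nm)
  expect_equal(attr(res2, "threshold"), attr(res, "threshold"))
  # photon conservation: events hold no more photons than their trace spans
  ev <- attr(res, "events")
  tr <- trace_from_tensor(tens)
  for (r in seq_len(nrow(ev))) {
    span <- sum(tr$photons[(ev$start[r] + 1):ev$end[r]])
    expect_equal(ev$total_photons[r], span)
  }
})

test_that("reconstruction renders unit-mass kernels at the localizations", {
  locs <- data.frame(x_nm = c(0, 40), y_nm = c(0, 0))
  img <- reconstruct(locs, kernel_sigma = 6, pixel_size = 1)
  # each kernel integrates to ~1
  expect_equal(sum(img$image), 2, tolerance = 1e-3)
  # two localizations 40 nm apart with a 6 nm kernel are resolvable:
  # profile along y = 0 has two maxima separated by a dip
  iy <- which.min(abs(img$y))
  prof <- img$image[, iy]
  i0 <- which.min(abs(img$x)); i40 <- which.min(abs(img$x - 40))
  imid <- which.min(abs(img$x - 20))
  expect_gt(prof[i0], 2 * prof[imid])
  expect_gt(prof[i40], 2 * prof[imid])
  # rendered cluster second moment = raw spread + kernel width in quadrature
  set.seed(9)
  pts <- data.frame(x_nm = rnorm(400, 0, 5), y_nm = rnorm(400, 0, 5))
  img2 <- reconstruct(pts, kernel_sigma = 6, pixel_size = 1)
  wsum <- sum(img2$image)
  mx <- sum(img2$image * outer(img2$x, rep(1, length(img2$y)))) / wsum
  vx <- sum(img2$image * outer(img2$x^2, rep(1, length(img2$y)))) / wsum - mx^2
  expect_equal(sqrt(vx), sqrt(var(pts$x_nm) * 399 / 400 + 36), tolerance = 0.05)
})

test_that("cluster uncertainty is the rms of the per-axis variances", {
  same <- data.frame(x_nm = rep(5, 4), y_nm = rep(-2, 4), cluster = 1)
  expect_equal(cluster_uncertainty(same)$sigma_nm, 0)
  # var_x = 16, var_y = 9 -> sqrt(12.5) = 3.536
  df <- data.frame(x_nm = c(-4, 0, 4), y_nm = c(-3, 0, 3), cluster = "a")
  got <- cluster_uncertainty(df)$sigma_nm
  expect_equal(got, sqrt(12.5), tolerance = 1e-12)
  expect_equal(got, 3.536, tolerance = 1e-3)
  # singleton clusters are skipped
  df2 <- rbind(df, data.frame(x_nm = 0, y_nm = 0, cluster = "b"))
  expect_equal(nrow(cluster_uncertainty(df2)), 1)
})
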