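#' Emitter script: positions, brightness, and blinking
#'
#' Describes the ground-truth behavior of an emitter over time: a piecewise
#' constant trajectory given by waypoints (each waypoint holds from its time
#' until the next), an overall brightness multiplier per waypoint, and an
#' optional two-state on/off blinking process with exponentially distributed
#' sojourn times (DNA-PAINT-like transient binding; the default on-time of
#' such events is of order 100 ms).
#'
#' @param waypoints A data frame with columns `time_ms`, `x_nm`, `y_nm` and
#'   optionally `brightness` (default 1). Times must be strictly increasing
#'   and brightness non-negative.
#' @param blinking `NULL` for an always-on emitter, or
#'   `list(on_ms = , off_ms = )` mean sojourn times of the two states.
#' @return An object of class `emitter_script`.
#' @export
emitter_script <- function(waypoints, blinking = NULL) {
  waypoints <- tibble::as_tibble(waypoints)
  stopifnot(all(c("time_ms", "x_nm", "y_nm") %in% names(waypoints)))
  if (!"brightness" %in% names(waypoints)) waypoints$brightness <- 1
  if (any(diff(waypoints$time_ms) <= 0)) stop("waypoint times must be strictly increasing")
  if (any(waypoints$brightness < 0)) stop("brightness must be >= 0")
  if (!is.null(blinking)) stopifnot(blinking$on_ms > 0, blinking$off_ms > 0)
  structure(list(waypoints = waypoints, blinking = blinking),
            class = "emitter_script")
}

#' Waypoint scripts for stage-stepping experiments
#'
#' Builds the stepping patterns used to characterize the localization range:
#' `"grid"` visits a square grid of positions spanning the detector field of
#' view (default 7 x 7 positions, 100 nm apart, covering about
#' 600 x 600 nm^2); `"steps"` is a 1-D staircase along x (default 6 nm
#' increments); `"custom"` wraps user waypoints.
#'
#' @param kind `"grid"`, `"steps"` or `"custom"`.
#' @param step Step size in nm.
#' @param extent Grid side length in nm (`"grid"` only).
#' @param n_steps Number of staircase positions (`"steps"` only).
#' @param dwell_ms Time spent at each position.
#' @param start Starting position `c(x, y)` in nm.
#' @param waypoints For `kind = "custom"`.
#' @return An [emitter_script()].
#' @export
step_pattern <- function(kind = c("grid", "steps", "custom"), step = 100,
                         extent = 600, n_steps = 10L, dwell_ms = 500,
                         start = c(0, 0), waypoints = NULL) {
  kind <- match.arg(kind)
  if (kind == "custom") return(emitter_script(waypoints))
  stopifnot(step > 0, dwell_ms > 0)
  if (kind == "grid") {
    ax <- seq(-extent / 2, extent / 2, by = step)
    pos <- expand.grid(x_nm = ax, y_nm = ax)
    wp <- tibble::tibble(
      time_ms = (seq_len(nrow(pos)) - 1) * dwell_ms,
      x_nm = pos$x_nm + start[1], y_nm = pos$y_nm + start[2]
    )
  } else {
    i <- seq_len(n_steps) - 1
    wp <- tibble::tibble(
      time_ms = i * dwell_ms,
      x_nm = start[1] + i * step, y_nm = start[2]
    )
  }
  emitter_script(wp)
}

#' Expected photon counts per orbit for a static emitter
#'
#' `lambda_ij = rate * m_ij(r) / sum_ij m_ij(center) + bkg_rate / (N_c * N_d)`.
#' The signal normalization is anchored at the TCP center: an emitter at the
#' center with rate `R` produces `sum(lambda) = R + bkg_rate` photons per
#' orbit in expectation; elsewhere the total follows the sum of the MDFs, as
#' under constant illumination power.
#'
#' @param mdf An `mdf_set`.
#' @param x,y Emitter position, nm (scalars).
#' @param rate Signal photons per orbit for an emitter at the TCP center.
#' @param bkg_rate Background photons per orbit, uniform over `(i, j)`.
#' @return An `N_c x N_d` matrix of Poisson rates.
#' @export
expected_counts <- function(mdf, x, y, rate, bkg_rate = 0) {
  stopifnot(rate >= 0, bkg_rate >= 0)
  dims <- mdf_dims(mdf)
  s0 <- sum(mdf_probe(mdf, 0, 0))
  m <- mdf_probe(mdf, x, y)
  lam <- rate * m / s0 + bkg_rate / length(m)
  matrix(lam, nrow = dims[["n_positions"]], ncol = dims[["n_elements"]],
         byrow = TRUE)
}

#' Simulate a photon-count tensor for a scripted emitter
#'
#' Draws independent Poisson counts for every (orbit, angular position,
#' detector element) cell. The emitter position and brightness are taken
#' from the script at the midpoint of each angular dwell (dwell = period /
#' N_c, much shorter than any scripted dynamics); blinking states, when
#' enabled, are drawn as an alternating exponential renewal process starting
#' in the off state. Fully reproducible for a fixed seed.
#'
#' @param mdf An `mdf_set`.
#' @param script An [emitter_script()].
#' @param rate Signal photons per orbit at the TCP center (see
#'   [expected_counts()]).
#' @param bkg_rate Background photons per orbit.
#' @param n_orbits Number of orbits to simulate.
#' @param seed Integer seed; required, to keep every simulation reproducible.
#' @param t0_ms Acquisition start time on the script clock.
#' @return An object of class `count_tensor`: integer array
#'   `counts[N_t, N_c, N_d]` plus orbit/detector metadata and the ground
#'   truth per-orbit emitter state.
#' @export
simulate_trace <- function(mdf, script, rate, bkg_rate = 0, n_orbits,
                           seed, t0_ms = 0) {
  stopifnot(inherits(mdf, "mdf_set"), inherits(script, "emitter_script"),
            n_orbits >= 1)
  if (missing(seed)) stop("an explicit seed is required")
  dims <- mdf_dims(mdf)
  nc <- dims[["n_positions"]]
  nd <- dims[["n_elements"]]
  period <- mdf$orbit$period_ms
  total_ms <- n_orbits * period
  s0 <- sum(mdf_probe(mdf, 0, 0))
  wp <- script$waypoints

  withr::with_seed(seed, {
    # blinking state changepoints over the full acquisition
    if (!is.null(script$blinking)) {
      times <- numeric(0)
      t <- 0
      state_on <- FALSE  # start off
      repeat {
        dt <- stats::rexp(1, 1 / (if (state_on) script$blinking$on_ms else script$blinking$off_ms))
        t <- t + dt
        if (t >= total_ms + t0_ms) break
        times <- c(times, t)
        state_on <- !state_on
      }
      state_at <- function(tt) (findInterval(tt, times) %% 2) == 1
    } else {
      state_at <- function(tt) rep(TRUE, length(tt))
    }

    # midpoint time of each angular dwell
    orbit_idx <- rep(seq_len(n_orbits) - 1L, each = nc)
    pos_idx <- rep(seq_len(nc) - 1L, times = n_orbits)
    t_mid <- t0_ms + orbit_idx * period + (pos_idx + 0.5) * period / nc
    seg <- findInterval(t_mid, wp$time_ms, rightmost.closed = FALSE)
    seg[seg < 1] <- 1L
    xe <- wp$x_nm[seg]
    ye <- wp$y_nm[seg]
    bright <- wp$brightness[seg] * as.numeric(state_at(t_mid))

    # m_ij at the dwell's own orbit position only
    off <- orbit_offsets(mdf$orbit)
    g <- mdf$base$grid
    act <- active_elements(mdf$base$det) + 1L
    vals <- mdf$base$values[, act, drop = FALSE]
    m <- .bilerp(vals, g$n, g$axis[1], g$pixel_size,
                 xe - off$dx_nm[pos_idx + 1L], ye - off$dy_nm[pos_idx + 1L])
    lam <- bright * rate * m / s0 + bkg_rate / (nc * nd)
    counts <- array(stats::rpois(length(lam), lam),
                    dim = c(nc, n_orbits, nd))  # filled dwell-major
  })
  # reorder to [N_t, N_c, N_d]
  counts <- aperm(array(counts, c(nc, n_orbits, nd)), c(2, 1, 3))
  truth <- tibble::tibble(
    orbit = seq_len(n_orbits) - 1L,
    x_nm = xe[seq(1, length(xe), by = nc)],
    y_nm = ye[seq(1, length(ye), by = nc)],
    on = tapply(bright > 0, orbit_idx, any)[as.character(seq_len(n_orbits) - 1L)] |> as.vector()
  )
  structure(
    list(counts = counts, orbit = mdf$orbit, det = mdf$base$det,
         t0_ms = t0_ms, seed = seed, rate = rate, bkg_rate = bkg_rate,
         truth = truth),
    class = "count_tensor"
  )
}

#' @export
print.count_tensor <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<count_tensor> %d orbits x %d positions x %d elements, %d photons total\n",
              d[1], d[2], d[3], sum(x$counts)))
  invisible(x)
}

#' Write / read a count tensor as long-format CSV
#'
#' One row per nonzero cell: `orbit`, `position`, `element`, `count`
#' (0-based indices), plus a JSON sidecar with geometry and acquisition
#' metadata.
#'
#' @param tensor A `count_tensor`.
#' @param path Path without extension; writes `<path>.csv` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_count_tensor <- function(tensor, path) {
  d <- dim(tensor$counts)
  idx <- which(tensor$counts > 0, arr.ind = TRUE)
  df <- data.frame(orbit = idx[, 1] - 1L, position = idx[, 2] - 1L,
                   element = idx[, 3] - 1L,
                   count = tensor$counts[idx])
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  meta <- list(dim = d, orbit = unclass(tensor$orbit),
               detector = unclass(tensor$det), t0_ms = tensor$t0_ms,
               seed = tensor$seed, rate = tensor$rate,
               bkg_rate = tensor$bkg_rate)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_count_tensor
#' @export
read_count_tensor <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(path, ".csv"))
  counts <- array(0L, dim = meta$dim)
  counts[cbind(df$orbit + 1L, df$position + 1L, df$element + 1L)] <- df$count
  det <- detector_geometry(meta$detector$n_rows, meta$detector$n_cols,
                           meta$detector$pitch, meta$detector$element_size,
                           meta$detector$excluded_elements)
  orbit <- orbit_geometry(meta$orbit$L, meta$orbit$alpha0,
                          meta$orbit$direction, meta$orbit$n_positions,
                          meta$orbit$period_ms)
  structure(
    list(counts = counts, orbit = orbit, det = det, t0_ms = meta$t0_ms,
         seed = meta$seed, rate = meta$rate, bkg_rate = meta$bkg_rate,
         truth = NULL),
    class = "count_tensor"
  )
}

#' Blinking nanoruler script
#'
#' Emulates DNA-PAINT imaging of a multi-site nanoruler: binding events
#' occur one at a time, each at one of the docking sites (cycled through in
#' turn), with exponentially distributed on- and off-times. The result is a
#' waypoint script whose brightness is 1 during events and 0 between them,
#' so no separate blinking process is needed in [simulate_trace()].
#'
#' @param sites A data frame with columns `x_nm`, `y_nm` (one row per
#'   docking site).
#' @param on_ms,off_ms Mean event duration and mean dark time between
#'   events, ms.
#' @param duration_ms Total script duration.
#' @param seed Integer seed.
#' @return An [emitter_script()] with an attribute `events`: a tibble of the
#'   true events (`t_on`, `t_off`, `site`).
#' @export
nanoruler_script <- function(sites, on_ms = 100, off_ms = 400,
                             duration_ms = 30000, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  sites <- tibble::as_tibble(sites)
  stopifnot(nrow(sites) >= 1, on_ms > 0, off_ms > 0)
  withr::with_seed(seed, {
    t <- stats::rexp(1, 1 / off_ms)
    k <- 0L
    ev <- list()
    while (t < duration_ms) {
      dur <- stats::rexp(1, 1 / on_ms)
      site <- (k %% nrow(sites)) + 1L
      ev[[length(ev) + 1L]] <- tibble::tibble(
        t_on = t, t_off = min(t + dur, duration_ms), site = site)
      k <- k + 1L
      t <- t + dur + stats::rexp(1, 1 / off_ms)
    }
  })
  events <- dplyr::bind_rows(ev)
  if (nrow(events) == 0) stop("no events generated; increase duration_ms")
  wp <- tibble::tibble(time_ms = 0, x_nm = sites$x_nm[1], y_nm = sites$y_nm[1],
                       brightness = 0)
  for (r in seq_len(nrow(events))) {
    s <- events$site[r]
    wp <- dplyr::bind_rows(
      wp,
      tibble::tibble(time_ms = events$t_on[r], x_nm = sites$x_nm[s],
                     y_nm = sites$y_nm[s], brightness = 1),
      tibble::tibble(time_ms = events$t_off[r], x_nm = sites$x_nm[s],
                     y_nm = sites$y_nm[s], brightness = 0)
    )
  }
  out <- emitter_script(wp)
  attr(out, "events") <- events
  out
}
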