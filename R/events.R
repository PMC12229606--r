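#' Per-orbit intensity trace
#'
#' Sums all photons over detector elements and orbit positions, per orbit,
#' optionally excluding further detector elements (e.g. high-dark-count
#' pixels) on top of those already excluded in the tensor's geometry.
#'
#' @param tensor A `count_tensor`.
#' @param excluded_elements Extra 0-based element indices to drop, referring
#'   to the tensor's active-element geometry.
#' @return A tibble with columns `orbit` (0-based) and `photons`.
#' @export
trace_from_tensor <- function(tensor, excluded_elements = integer()) {
  stopifnot(inherits(tensor, "count_tensor"))
  act <- active_elements(tensor$det)
  keep <- which(!act %in% excluded_elements)
  photons <- apply(tensor$counts[, , keep, drop = FALSE], 1, sum)
  tibble::tibble(orbit = seq_along(photons) - 1L, photons = as.integer(photons))
}

.trace_photons <- function(trace) {
  if (is.data.frame(trace)) trace$photons else as.numeric(trace)
}

#' Intensity threshold from a two-Gaussian histogram fit
#'
#' Fits the histogram of per-orbit photon counts with a sum of two Gaussian
#' components (background and signal modes). The default threshold is the
#' mean of the lower component ("first peak"); the `"valley"` method instead
#' returns the minimum of the fitted curve between the two component means.
#'
#' @param trace A trace tibble from [trace_from_tensor()] or a numeric
#'   vector of per-orbit counts.
#' @param method `"first_peak"` (default) or `"valley"`.
#' @param bins Number of histogram bins.
#' @param manual If supplied, returned unchanged (manual override).
#' @return The threshold (photons per orbit), with the fitted component
#'   parameters in attribute `"fit"`.
#' @export
fit_threshold <- function(trace, method = c("first_peak", "valley"),
                          bins = 60L, manual = NULL) {
  if (!is.null(manual)) return(manual)
  method <- match.arg(method)
  x <- .trace_photons(trace)
  h <- graphics::hist(x, breaks = bins, plot = FALSE)
  mid <- h$mids
  cnt <- h$counts
  # initialize the two modes by splitting at the overall median of the data
  split <- stats::median(x)
  lo <- x[x <= split]
  hi <- x[x > split]
  if (length(unique(lo)) < 2 || length(unique(hi)) < 2) {
    stop("trace histogram does not show two distinguishable modes; supply a manual threshold")
  }
  start <- list(a1 = max(cnt[mid <= split]), m1 = mean(lo),
                s1 = max(stats::sd(lo), diff(mid[1:2])),
                a2 = max(cnt[mid > split]), m2 = mean(hi),
                s2 = max(stats::sd(hi), diff(mid[1:2])))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      cnt ~ a1 * exp(-(mid - m1)^2 / (2 * s1^2)) +
        a2 * exp(-(mid - m2)^2 / (2 * s2^2)),
      start = start,
      lower = c(0, min(mid), 0, 0, min(mid), 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("two-Gaussian histogram fit failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  p <- as.list(stats::coef(fit))
  if (abs(p$m1 - p$m2) < 2 * max(p$s1, p$s2)) {
    stop("fitted components overlap too much (unimodal histogram?); supply a manual threshold")
  }
  lower_mean <- min(p$m1, p$m2)
  thr <- if (method == "first_peak") {
    lower_mean
  } else {
    grid <- seq(min(p$m1, p$m2), max(p$m1, p$m2), length.out = 512)
    f <- p$a1 * exp(-(grid - p$m1)^2 / (2 * p$s1^2)) +
      p$a2 * exp(-(grid - p$m2)^2 / (2 * p$s2^2))
    grid[which.min(f)]
  }
  structure(thr, fit = p)
}

#' Segment a trace into above-threshold events
#'
#' Maximal contiguous runs of orbits with `photons > threshold`. Intervals
#' are half-open, 0-based orbit indices: an event `[start, end)` covers
#' orbits `start` to `end - 1`.
#'
#' @param trace A trace tibble or numeric vector.
#' @param threshold Photon threshold (strictly exceeded to be inside an
#'   event).
#' @return A tibble with columns `event` (1-based id), `start`, `end`.
#' @export
segment_events <- function(trace, threshold) {
  stopifnot(threshold >= 0)
  x <- .trace_photons(trace)
  above <- x > threshold
  if (!any(above)) {
    return(tibble::tibble(event = integer(), start = integer(), end = integer()))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  tibble::tibble(event = seq_along(on),
                 start = starts[on] - 1L, end = ends[on])
}

#' Event filter configuration
#'
#' The defaults are the thresholds of the origami analysis: at least 2000
#' photons per event, at least 5 orbits duration, per-orbit count
#' fluctuations below 2.5 times the Poisson expectation `sqrt(N)`, and a
#' three-segment consistency threshold `sigma < 8.25` nm (5 nm for the
#' tighter analysis).
#'
#' @param min_photons Minimum total photons per event.
#' @param min_orbits Minimum event duration in orbits.
#' @param poisson_factor Maximum allowed ratio of the per-orbit count
#'   standard deviation to `sqrt(mean per-orbit count)`.
#' @param sigma_threshold Acceptance threshold on the three-segment spread
#'   `sigma`, nm.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_photons = 2000, min_orbits = 5,
                          poisson_factor = 2.5, sigma_threshold = 8.25) {
  stopifnot(min_photons > 0, min_orbits > 0, poisson_factor > 0,
            sigma_threshold > 0)
  structure(list(min_photons = min_photons, min_orbits = min_orbits,
                 poisson_factor = poisson_factor,
                 sigma_threshold = sigma_threshold),
            class = "filter_config")
}

#' Apply the event filters
#'
#' Adds, per event: the total photon count, duration, per-orbit count
#' standard deviation, and the three verdicts — (i) `total_photons >=
#' min_photons`, (ii) `duration >= min_orbits`, (iii) `per_orbit_std <=
#' poisson_factor * sqrt(mean per-orbit count)`. `pass_all` requires all
#' three.
#'
#' @param events Event table from [segment_events()].
#' @param trace The trace the events were segmented from.
#' @param cfg A [filter_config()].
#' @return The event table with columns `total_photons`, `duration_orbits`,
#'   `per_orbit_std`, `pass_photons`, `pass_duration`, `pass_poisson`,
#'   `pass_all`.
#' @export
apply_filters <- function(events, trace, cfg = filter_config()) {
  x <- .trace_photons(trace)
  stats_tbl <- purrr::pmap(list(events$start, events$end), function(s, e) {
    seg <- x[(s + 1L):e]
    tibble::tibble(total_photons = sum(seg),
                   duration_orbits = length(seg),
                   per_orbit_std = if (length(seg) > 1) stats::sd(seg) else 0)
  })
  out <- dplyr::bind_cols(events, dplyr::bind_rows(stats_tbl))
  out$pass_photons <- out$total_photons >= cfg$min_photons
  out$pass_duration <- out$duration_orbits >= cfg$min_orbits
  out$pass_poisson <- out$per_orbit_std <=
    cfg$poisson_factor * sqrt(out$total_photons / out$duration_orbits)
  out$pass_all <- out$pass_photons & out$pass_duration & out$pass_poisson
  out
}

# Split d orbits into 3 segments as equal as possible; the last segment
# absorbs the remainder.
.segment_bounds <- function(start, end) {
  d <- end - start
  len <- d %/% 3L
  s1 <- start; s2 <- start + len; s3 <- start + 2L * len
  cbind(start = c(s1, s2, s3), end = c(s2, s3, end))
}

#' Three-segment localization of filtered events
#'
#' Each event is split into three equally long segments (orbit-wise; the
#' last segment absorbs the remainder). Each segment is localized by
#' [localize_mle()]; the event-level spread
#' `sigma = sqrt(0.5 * (sigma_x^2 + sigma_y^2))` uses the sample (n - 1)
#' standard deviation of the three segment positions. The event is
#' accepted if `sigma < cfg$sigma_threshold`, and its final position is the
#' mean of the three segment positions.
#'
#' @param events Filtered event table ([apply_filters()]); only rows with
#'   `pass_all` are localized.
#' @param tensor The `count_tensor` the events come from.
#' @param mdf An `mdf_set`.
#' @param bkg A [background_model()] or SBR value.
#' @param cfg A [filter_config()].
#' @param excluded_elements As in [trace_from_tensor()].
#' @param search As in [localize_mle()].
#' @return A tibble of class `ismflux_events`, one row per localized event:
#'   `event`, `start`, `end`, `x_nm`, `y_nm`, `total_photons`, `sigma_nm`,
#'   `accepted`, `degenerate`, and a list-column `segments` holding the
#'   three segment localizations.
#' @export
localize_events <- function(events, tensor, mdf, bkg, cfg = filter_config(),
                            excluded_elements = integer(), search = NULL) {
  stopifnot(inherits(tensor, "count_tensor"))
  keep <- if ("pass_all" %in% names(events)) which(events$pass_all) else seq_len(nrow(events))
  act <- active_elements(tensor$det)
  el_keep <- which(!act %in% excluded_elements)
  rows <- purrr::map(keep, function(r) {
    s <- events$start[r]; e <- events$end[r]
    b <- .segment_bounds(s, e)
    segs <- purrr::map(seq_len(3), function(k) {
      if (b[k, "end"] <= b[k, "start"]) return(NULL)
      n <- event_matrix(tensor$counts[(b[k, "start"] + 1L):b[k, "end"], , el_keep,
                                      drop = FALSE])
      if (sum(n) < 1) return(NULL)
      loc <- localize_mle(n, mdf, bkg, search)
      loc$segment <- k
      loc
    })
    degenerate <- any(vapply(segs, is.null, logical(1)))
    if (degenerate) {
      return(tibble::tibble(event = events$event[r], start = s, end = e,
                            x_nm = NA_real_, y_nm = NA_real_,
                            total_photons = events$total_photons[r],
                            sigma_nm = NA_real_, accepted = FALSE,
                            degenerate = TRUE, segments = list(NULL)))
    }
    segs <- dplyr::bind_rows(segs)
    sigma <- sqrt(0.5 * (stats::var(segs$x_nm) + stats::var(segs$y_nm)))
    tibble::tibble(event = events$event[r], start = s, end = e,
                   x_nm = mean(segs$x_nm), y_nm = mean(segs$y_nm),
                   total_photons = sum(segs$n_photons),
                   sigma_nm = sigma, accepted = sigma < cfg$sigma_threshold,
                   degenerate = FALSE, segments = list(segs))
  })
  tibble::new_tibble(dplyr::bind_rows(rows), class = "ismflux_events")
}

#' Full event-detection pipeline
#'
#' Trace, threshold, segmentation, filtering and three-segment localization
#' in one call.
#'
#' @inheritParams localize_events
#' @param threshold Manual threshold; default fitted by [fit_threshold()].
#' @return As [localize_events()]; the filtered event table is attached as
#'   attribute `"events"` and the threshold as `"threshold"`.
#' @export
run_pipeline <- function(tensor, mdf, bkg, cfg = filter_config(),
                         excluded_elements = integer(), threshold = NULL,
                         search = NULL) {
  trace <- trace_from_tensor(tensor, excluded_elements)
  thr <- fit_threshold(trace, manual = threshold)
  ev <- segment_events(trace, thr)
  ev <- apply_filters(ev, trace, cfg)
  out <- localize_events(ev, tensor, mdf, bkg, cfg, excluded_elements, search)
  attr(out, "events") <- ev
  attr(out, "threshold") <- as.numeric(thr)
  out
}

#' Render localizations as a Gaussian-kernel image
#'
#' Sums an isotropic Gaussian kernel of fixed standard deviation at every
#' localization position.
#'
#' @param locs A data frame with `x_nm`, `y_nm` (e.g. accepted events).
#' @param kernel_sigma Kernel standard deviation, nm.
#' @param pixel_size Rendering pixel size, nm.
#' @param extent Optional `c(xmin, xmax, ymin, ymax)`; default the
#'   localization bounding box padded by `4 * kernel_sigma`.
#' @return An object of class `ismflux_render`: the image matrix (`[x, y]`),
#'   axes, and parameters. Each kernel integrates to ~1 over the image.
#' @export
reconstruct <- function(locs, kernel_sigma = 6, pixel_size = 2,
                        extent = NULL) {
  stopifnot(nrow(locs) >= 1, kernel_sigma > 0, pixel_size > 0)
  pad <- 4 * kernel_sigma
  if (is.null(extent)) {
    extent <- c(min(locs$x_nm) - pad, max(locs$x_nm) + pad,
                min(locs$y_nm) - pad, max(locs$y_nm) + pad)
  }
  xs <- seq(extent[1], extent[2], by = pixel_size)
  ys <- seq(extent[3], extent[4], by = pixel_size)
  img <- matrix(0, length(xs), length(ys))
  for (r in seq_len(nrow(locs))) {
    kx <- stats::dnorm(xs, locs$x_nm[r], kernel_sigma)
    ky <- stats::dnorm(ys, locs$y_nm[r], kernel_sigma)
    img <- img + outer(kx, ky) * pixel_size^2
  }
  structure(list(image = img, x = xs, y = ys, kernel_sigma = kernel_sigma,
                 pixel_size = pixel_size),
            class = "ismflux_render")
}

#' Per-cluster localization uncertainty
#'
#' For localizations grouped into clusters (sites), computes per cluster
#' `sqrt((var_x + var_y) / 2)` — the rms of the per-axis spreads — plus the
#' mean and standard deviation across clusters. Clusters with fewer than two
#' localizations are skipped.
#'
#' @param locs Data frame with `x_nm`, `y_nm` and a cluster column.
#' @param cluster Name of the cluster column (default `"cluster"`).
#' @return A tibble (`cluster`, `n`, `x_mean`, `y_mean`, `sigma_nm`) with
#'   attributes `mean_sigma` and `sd_sigma`.
#' @export
cluster_uncertainty <- function(locs, cluster = "cluster") {
  stopifnot(cluster %in% names(locs))
  out <- locs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cluster))) |>
    dplyr::summarise(
      n = dplyr::n(),
      x_mean = mean(.data$x_nm), y_mean = mean(.data$y_nm),
      sigma_nm = sqrt((stats::var(.data$x_nm) + stats::var(.data$y_nm)) / 2),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n >= 2)
  attr(out, "mean_sigma") <- mean(out$sigma_nm)
  attr(out, "sd_sigma") <- stats::sd(out$sigma_nm)
  out
}

#' Write localizations to CSV
#'
#' @param locs An event localization table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path) {
  flat <- locs[setdiff(names(locs), "segments")]
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}
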