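#' Background mixing model
#'
#' Background photons are assumed uniformly distributed over all orbit
#' positions and detector elements. The signal-to-background ratio `sbr`
#' mixes the MDF-derived detection probabilities with that uniform floor:
#' with weight `sbr / (sbr + 1)` on the signal and `1 / (sbr + 1)` on the
#' background.
#'
#' @param sbr Signal-to-background ratio, > 0. `Inf` means no background.
#' @return An object of class `background_model`.
#' @export
background_model <- function(sbr = 10) {
  stopifnot(sbr > 0)
  structure(list(sbr = sbr), class = "background_model")
}

.as_sbr <- function(bkg) {
  if (inherits(bkg, "background_model")) bkg$sbr else as.numeric(bkg)
}

#' Photon detection probabilities at candidate emitter positions
#'
#' Evaluates `p_ij(r) = sbr/(sbr+1) * m_ij(r)/sum(m(r)) + 1/(sbr+1) * 1/(Nc*Nd)`
#' where `m_ij` are the MDF values. Each row sums to 1 to machine precision.
#'
#' @param mdf An `mdf_set`.
#' @param bkg A [background_model()] or a plain SBR value.
#' @param x,y Candidate emitter coordinates (nm, equal-length vectors).
#' @return A `length(x) x (N_c * N_d)` matrix of probabilities, columns in
#'   the [mdf_probe()] order.
#' @export
detection_probabilities <- function(mdf, bkg, x, y) {
  sbr <- .as_sbr(bkg)
  m <- mdf_probe(mdf, x, y)
  s <- rowSums(m)
  if (is.infinite(sbr)) {
    if (any(s <= 0)) {
      stop("all MDF values are zero at a query position and sbr is infinite (degenerate)")
    }
    return(m / s)
  }
  k <- ncol(m)
  sig <- m / s
  sig[s <= 0, ] <- 1 / k  # fully degenerate signal: background floor only
  (sbr / (sbr + 1)) * sig + (1 / (sbr + 1)) / k
}

#' Reduce a count tensor (or array) to an event matrix
#'
#' Sums photon counts over the orbit axis, giving the `N_c x N_d` reduced
#' event matrix `n_ij` that enters the likelihood.
#'
#' @param counts A `count_tensor` (see [simulate_trace()]), or an array
#'   `N_t x N_c x N_d`, or an already-reduced `N_c x N_d` matrix.
#' @param orbits Optional orbit indices (0-based, as in event bounds) to sum
#'   over; default all.
#' @return An `N_c x N_d` integer matrix of class `event_matrix`.
#' @export
event_matrix <- function(counts, orbits = NULL) {
  if (inherits(counts, "count_tensor")) counts <- counts$counts
  if (is.matrix(counts)) {
    return(structure(counts, class = c("event_matrix", class(counts))))
  }
  stopifnot(length(dim(counts)) == 3)
  if (!is.null(orbits)) {
    counts <- counts[orbits + 1L, , , drop = FALSE]
  }
  m <- apply(counts, c(2, 3), sum)
  structure(m, class = c("event_matrix", class(m)))
}

#' Multinomial log-likelihood of an emitter position
#'
#' Evaluates `sum_ij n_ij * log p_ij(r)` for one or many candidate positions.
#' The count-only multinomial constant `log(N! / prod n_ij!)` is omitted, so
#' differences between positions (likelihood ratios) are exact but absolute
#' values are offset by a constant. Positions where some `p_ij = 0` with
#' `n_ij > 0` return `-Inf`.
#'
#' @param event An `N_c x N_d` count matrix (see [event_matrix()]).
#' @param mdf An `mdf_set`.
#' @param bkg A [background_model()] or SBR value.
#' @param x,y Candidate position(s), nm.
#' @return Numeric vector of log-likelihood values.
#' @export
log_likelihood <- function(event, mdf, bkg, x, y) {
  nvec <- as.vector(t(event))  # orbit-major, element-minor: matches probe order
  dims <- mdf_dims(mdf)
  if (length(nvec) != prod(dims)) {
    stop("event matrix dimensions do not match the MDF set")
  }
  p <- detection_probabilities(mdf, bkg, x, y)
  used <- nvec > 0
  ll <- log(p[, used, drop = FALSE]) %*% nvec[used]
  ll[!is.finite(ll)] <- -Inf
  as.vector(ll)
}

# Evaluate the log-likelihood on a candidate grid and return the best point
# with deterministic tie-breaking (lowest x, then lowest y).
.ll_argmax <- function(event, mdf, bkg, xs, ys) {
  cand <- expand.grid(y = ys, x = xs)  # x slowest => ordering favors low x, then low y
  cand <- cand[order(cand$x, cand$y), ]
  ll <- log_likelihood(event, mdf, bkg, cand$x, cand$y)
  best <- which.max(ll)
  list(x = cand$x[best], y = cand$y[best], ll = ll[best])
}

#' Maximum-likelihood localization of a reduced event
#'
#' Brute-force grid maximization of the multinomial likelihood: a coarse
#' exhaustive pass over the search region, followed by local refinement
#' passes with the step halved each level down to (at most) the MDF pixel
#' size. The search is derivative-free, deterministic, and ties break toward
#' the lowest x then lowest y.
#'
#' @param event An `N_c x N_d` count matrix with at least one photon.
#' @param mdf An `mdf_set`.
#' @param bkg A [background_model()] or SBR value.
#' @param search Optional list overriding the search specification:
#'   `x_range`, `y_range` (nm, default a square covering the detector
#'   footprint), `coarse_step` (nm, default 8 MDF pixels), `n_refine`
#'   (default 3 halving levels), `min_step` (refinement floor; default one
#'   MDF pixel, i.e. localization to the map resolution — calibration uses
#'   a finer floor).
#' @return A one-row tibble of class `ismflux_loc`: `x_nm`, `y_nm`,
#'   `loglik`, `n_photons`, `grid_level`, `on_border`, `degenerate`.
#' @examples
#' base <- simulate_base_mdf(grid = mdf_grid(2.5, 400))
#' mdf <- expand_orbit(base, orbit_geometry(L = 90))
#' lam <- expected_counts(mdf, x = 50, y = -20, rate = 600, bkg_rate = 60)
#' n <- matrix(rpois(length(lam), lam), nrow = nrow(lam))
#' localize_mle(n, mdf, bkg = 10)
#' @export
localize_mle <- function(event, mdf, bkg, search = NULL) {
  if (sum(event) < 1) stop("empty event: localization needs at least one photon")
  sp <- .search_spec(mdf, search)
  xs <- seq(sp$x_range[1], sp$x_range[2], by = sp$coarse_step)
  ys <- seq(sp$y_range[1], sp$y_range[2], by = sp$coarse_step)
  best <- .ll_argmax(event, mdf, bkg, xs, ys)
  step <- sp$coarse_step
  level <- 0L
  px <- sp$min_step
  for (lev in seq_len(sp$n_refine)) {
    new_step <- max(step / 2, px)
    xs <- best$x + seq(-step, step, by = new_step)
    ys <- best$y + seq(-step, step, by = new_step)
    xs <- xs[xs >= sp$x_range[1] & xs <= sp$x_range[2]]
    ys <- ys[ys >= sp$y_range[1] & ys <= sp$y_range[2]]
    best <- .ll_argmax(event, mdf, bkg, xs, ys)
    step <- new_step
    level <- lev
    if (step <= px) break
  }
  on_border <- best$x <= sp$x_range[1] || best$x >= sp$x_range[2] ||
    best$y <= sp$y_range[1] || best$y >= sp$y_range[2]
  tibble::new_tibble(
    tibble::tibble(
      x_nm = best$x, y_nm = best$y, loglik = best$ll,
      n_photons = sum(event), grid_level = level,
      on_border = on_border, degenerate = !is.finite(best$ll)
    ),
    class = "ismflux_loc"
  )
}

.search_spec <- function(mdf, search) {
  px <- mdf$base$grid$pixel_size
  centers <- element_centers(mdf$base$det)
  half <- max(abs(c(centers$x_nm, centers$y_nm))) + mdf$base$det$element_size / 2
  # stay inside the interpolable grid (orbit shift + 1 px margin)
  lim <- max(abs(mdf$base$grid$axis)) - mdf$orbit$L / 2 - 2 * px
  half <- min(half, lim)
  sp <- list(x_range = c(-half, half), y_range = c(-half, half),
             coarse_step = 8 * px, n_refine = 3L, min_step = px)
  if (!is.null(search)) sp[names(search)] <- search
  sp
}

#' Per-subset localization over orbit-angle partitions
#'
#' Localizes an event separately on subsets of orbit positions (for instance
#' the 4 quadrants of 8 consecutive positions used for orbit
#' self-calibration). For each subset, only the corresponding rows of the
#' event matrix and MDF pages are used and the detection probabilities are
#' renormalized over the subset with the same SBR mixture.
#'
#' @param event An `N_c x N_d` count matrix.
#' @param mdf An `mdf_set`.
#' @param bkg A [background_model()] or SBR value.
#' @param subsets A list of integer vectors of 0-based orbit positions that
#'   partition (or subset) `0:(N_c-1)`. Default: 4 quadrants of consecutive
#'   positions.
#' @param search As in [localize_mle()].
#' @return A tibble with one row per non-empty subset (`subset`, `x_nm`,
#'   `y_nm`, `loglik`, `n_photons`, `on_border`, `skipped`).
#' @export
localize_per_subset <- function(event, mdf, bkg, subsets = NULL, search = NULL) {
  nc <- mdf$orbit$n_positions
  if (is.null(subsets)) {
    per <- nc %/% 4L
    subsets <- split(0:(nc - 1L), rep(1:4, each = per, length.out = nc))
  }
  res <- purrr::imap(subsets, function(rows, nm) {
    sub_event <- event[rows + 1L, , drop = FALSE]
    if (sum(sub_event) < 1) {
      return(tibble::tibble(subset = as.character(nm), x_nm = NA_real_,
                            y_nm = NA_real_, loglik = NA_real_,
                            n_photons = 0L, on_border = NA, skipped = TRUE))
    }
    sub_mdf <- .subset_orbit(mdf, rows)
    loc <- localize_mle(sub_event, sub_mdf, bkg, search)
    tibble::tibble(subset = as.character(nm), x_nm = loc$x_nm, y_nm = loc$y_nm,
                   loglik = loc$loglik, n_photons = loc$n_photons,
                   on_border = loc$on_border, skipped = FALSE)
  })
  dplyr::bind_rows(res)
}

# Restrict an mdf_set to a subset of orbit positions: represented as a new
# orbit whose offsets are exactly the selected delta_i. We keep the base and
# record explicit offsets.
.subset_orbit <- function(mdf, rows) {
  off <- orbit_offsets(mdf$orbit)[rows + 1L, , drop = FALSE]
  out <- mdf
  out$orbit <- structure(
    list(L = mdf$orbit$L, alpha0 = mdf$orbit$alpha0,
         direction = mdf$orbit$direction, n_positions = nrow(off),
         period_ms = mdf$orbit$period_ms, explicit_offsets = off),
    class = "orbit_geometry"
  )
  out
}
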