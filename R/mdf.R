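#' Sample-plane pixel grid for MDF maps
#'
#' Coordinates are sample-plane nm with the origin at the center of the
#' targeted coordinate pattern, x to the right and y up. Pixel centers sit at
#' half-integer multiples of the pixel size, symmetric around the origin.
#'
#' @param pixel_size Pixel size in nm. The simulated-MDF default is 2.5 nm;
#'   measured MDFs typically use 2 nm.
#' @param n_pixels Number of pixels per side (square grid).
#' @return An object of class `mdf_grid` with fields `pixel_size`, `n` and the
#'   pixel-center coordinate `axis`.
#' @export
mdf_grid <- function(pixel_size = 2.5, n_pixels = 1000L) {
  stopifnot(pixel_size > 0, n_pixels >= 4)
  n <- as.integer(n_pixels)
  axis <- (seq_len(n) - 0.5 - n / 2) * pixel_size
  structure(list(pixel_size = pixel_size, n = n, axis = axis),
            class = "mdf_grid")
}

#' @export
print.mdf_grid <- function(x, ...) {
  cat(sprintf("<mdf_grid> %d x %d px, %g nm/px, extent [%g, %g] nm\n",
              x$n, x$n, x$pixel_size, min(x$axis), max(x$axis)))
  invisible(x)
}

# Bilinear interpolation of a stack of maps (columns of `values`, each a
# flattened n x n image, x fastest) at scattered points. Values are clipped
# at zero after interpolation. Points must lie strictly within the outermost
# pixel centers.
.bilerp <- function(values, n, axis1, px, xq, yq) {
  fx <- (xq - axis1) / px + 1
  fy <- (yq - axis1) / px + 1
  if (any(fx < 1 | fx > n | fy < 1 | fy > n)) {
    stop("query point outside the MDF grid (increase the grid or shrink the search region)")
  }
  ix <- pmin(floor(fx), n - 1)
  iy <- pmin(floor(fy), n - 1)
  tx <- fx - ix
  ty <- fy - iy
  i11 <- (iy - 1) * n + ix
  v <- (1 - tx) * (1 - ty) * values[i11, , drop = FALSE] +
    tx * (1 - ty) * values[i11 + 1, , drop = FALSE] +
    (1 - tx) * ty * values[i11 + n, , drop = FALSE] +
    tx * ty * values[i11 + n + 1, , drop = FALSE]
  v[v < 0] <- 0
  v
}

#' Simulate the base molecule detection functions
#'
#' Computes the stack of detection maps `I_0j(r) = Exc(r) * Det_j(r)` for the
#' beam parked at the origin: `Exc` is the parametric excitation doughnut
#' centered at the origin and `Det_j` is the detection PSF integrated over
#' element `j`'s square active area. Detection is descanned, so the element
#' offsets are fixed in sample space and the whole product translates rigidly
#' with the beam (see [expand_orbit()]). The stack is normalized so that
#' `sum_j I_0j` equals 1 at the doughnut intensity maximum `(w / sqrt(2), 0)`.
#'
#' @param optics An [optics_model()].
#' @param det A [detector_geometry()]. All elements are simulated; excluded
#'   elements are dropped later, at likelihood evaluation.
#' @param grid An [mdf_grid()]. Must cover the detector footprint.
#' @return An object of class `mdf_base`: the flattened `n^2 x N_d` map stack
#'   plus grid/detector/optics metadata.
#' @examples
#' base <- simulate_base_mdf(grid = mdf_grid(2.5, 400))
#' mdf <- expand_orbit(base, orbit_geometry(L = 90))
#' @export
simulate_base_mdf <- function(optics = optics_model(),
                              det = detector_geometry(),
                              grid = mdf_grid()) {
  stopifnot(inherits(optics, "optics_model"), inherits(det, "detector_geometry"),
            inherits(grid, "mdf_grid"))
  centers <- element_centers(det)
  half_extent <- max(abs(grid$axis))
  footprint <- max(abs(c(centers$x_nm, centers$y_nm))) + det$element_size / 2
  if (half_extent < footprint) {
    stop(sprintf("grid half-extent %.0f nm is smaller than the detector footprint %.0f nm",
                 half_extent, footprint))
  }
  w <- optics$doughnut_waist
  sd_det <- optics$detection_sigma
  half <- det$element_size / 2
  exc <- outer(grid$axis, grid$axis,
               function(x, y) doughnut_profile(sqrt(x^2 + y^2), optics))
  n_el <- nrow(centers)
  values <- matrix(0, grid$n^2, n_el)
  det1d <- function(u, c0) {
    stats::pnorm((u - c0 + half) / sd_det) - stats::pnorm((u - c0 - half) / sd_det)
  }
  for (j in seq_len(n_el)) {
    values[, j] <- as.vector(
      exc * outer(det1d(grid$axis, centers$x_nm[j]),
                  det1d(grid$axis, centers$y_nm[j]))
    )
  }
  base <- structure(
    list(values = values, grid = grid, det = det, optics = optics),
    class = "mdf_base"
  )
  # normalize: total detection probability = 1 at the doughnut maximum
  s <- sum(.bilerp(values, grid$n, grid$axis[1], grid$pixel_size,
                   w / sqrt(2), 0))
  base$values <- base$values / s
  base
}

#' Wrap an existing map stack as a base MDF
#'
#' For measured or externally computed `I_0j` stacks.
#'
#' @param maps A `n x n x N_d` array, or list of `n x n` matrices, indexed
#'   `[x, y]` on the grid axes.
#' @param grid,det As in [simulate_base_mdf()].
#' @param optics Optional [optics_model()] provenance.
#' @return An `mdf_base`.
#' @export
as_mdf_base <- function(maps, grid, det, optics = NULL) {
  if (is.list(maps)) maps <- simplify2array(maps)
  stopifnot(length(dim(maps)) == 3)
  if (dim(maps)[1] != grid$n || dim(maps)[2] != grid$n) {
    stop("map dimensions do not match the grid")
  }
  if (dim(maps)[3] != det$n_rows * det$n_cols) {
    stop("number of maps does not match the detector geometry")
  }
  if (any(maps < 0)) stop("MDF values must be non-negative")
  structure(
    list(values = matrix(maps, nrow = grid$n^2), grid = grid, det = det,
         optics = optics),
    class = "mdf_base"
  )
}

#' @export
print.mdf_base <- function(x, ...) {
  cat(sprintf("<mdf_base> %d maps of %d x %d px (%g nm/px)\n",
              ncol(x$values), x$grid$n, x$grid$n, x$grid$pixel_size))
  invisible(x)
}

#' Expand a base MDF stack over the orbit positions
#'
#' The full MDF set has `values[i][j](r) = I_0j(r - delta_i)`, the base map
#' translated to orbit position `i`. The translation is exact by
#' construction: the set stores the base stack together with the orbit and
#' applies the shift when a map is evaluated (bilinear interpolation for
#' subpixel offsets, values clipped at zero). [mdf_page()] materializes any
#' single shifted map.
#'
#' @param base An `mdf_base` (from [simulate_base_mdf()] or [as_mdf_base()]).
#' @param orbit An [orbit_geometry()]. The orbit radius must leave at least a
#'   one-pixel interpolation margin inside the grid.
#' @param provenance `"simulated"` or `"measured"`.
#' @return An object of class `mdf_set`.
#' @export
expand_orbit <- function(base, orbit, provenance = "simulated") {
  stopifnot(inherits(base, "mdf_base"), inherits(orbit, "orbit_geometry"))
  margin <- max(abs(base$grid$axis)) - base$grid$pixel_size
  if (orbit$L / 2 >= margin) {
    stop("orbit radius exceeds the usable grid margin")
  }
  provenance <- match.arg(provenance, c("simulated", "measured"))
  structure(
    list(base = base, orbit = orbit, provenance = provenance),
    class = "mdf_set"
  )
}

#' @export
print.mdf_set <- function(x, ...) {
  nd <- length(active_elements(x$base$det))
  cat(sprintf("<mdf_set> %s, N_c = %d x N_d = %d maps, grid %d px @ %g nm, L = %g nm\n",
              x$provenance, x$orbit$n_positions, nd,
              x$base$grid$n, x$base$grid$pixel_size, x$orbit$L))
  invisible(x)
}

#' Number of orbit positions and active detector elements of an MDF set
#'
#' @param mdf An `mdf_set`.
#' @return Named integer vector `c(n_positions, n_elements)`.
#' @export
mdf_dims <- function(mdf) {
  c(n_positions = mdf$orbit$n_positions,
    n_elements = length(active_elements(mdf$base$det)))
}

#' Evaluate all MDF maps at scattered emitter positions
#'
#' Returns the raw (unnormalized) detection values `m_ij(r)` for every orbit
#' position i and active detector element j, by bilinear interpolation of the
#' base stack at `r - delta_i`.
#'
#' @param mdf An `mdf_set`.
#' @param x,y Emitter coordinates in nm (vectors of equal length).
#' @return A `length(x) x (N_c * N_d)` matrix; columns ordered orbit-position
#'   major, detector-element minor.
#' @export
mdf_probe <- function(mdf, x, y) {
  stopifnot(inherits(mdf, "mdf_set"), length(x) == length(y))
  g <- mdf$base$grid
  act <- active_elements(mdf$base$det) + 1L
  vals <- mdf$base$values[, act, drop = FALSE]
  off <- orbit_offsets(mdf$orbit)
  nc <- mdf$orbit$n_positions
  nd <- length(act)
  out <- matrix(0, length(x), nc * nd)
  for (i in seq_len(nc)) {
    out[, ((i - 1) * nd + 1):(i * nd)] <-
      .bilerp(vals, g$n, g$axis[1], g$pixel_size,
              x - off$dx_nm[i], y - off$dy_nm[i])
  }
  out
}

#' Materialize one shifted MDF map
#'
#' @param mdf An `mdf_set`.
#' @param position Orbit position index (0-based).
#' @param element Detector element index (0-based, must be active).
#' @return An `n x n` matrix (`[x, y]` indexing) of the map
#'   `I_0j(r - delta_i)`; grid points whose source coordinate falls outside
#'   the grid are set to 0.
#' @export
mdf_page <- function(mdf, position, element) {
  stopifnot(inherits(mdf, "mdf_set"))
  g <- mdf$base$grid
  if (!position %in% (seq_len(mdf$orbit$n_positions) - 1L)) {
    stop("invalid orbit position")
  }
  if (!element %in% active_elements(mdf$base$det)) stop("invalid or excluded element")
  off <- orbit_offsets(mdf$orbit)
  dx <- off$dx_nm[position + 1L]
  dy <- off$dy_nm[position + 1L]
  xq <- rep(g$axis, times = g$n) - dx
  yq <- rep(g$axis, each = g$n) - dy
  ok <- xq >= g$axis[1] & xq <= g$axis[g$n] & yq >= g$axis[1] & yq <= g$axis[g$n]
  v <- numeric(g$n^2)
  v[ok] <- .bilerp(mdf$base$values[, element + 1L, drop = FALSE],
                   g$n, g$axis[1], g$pixel_size, xq[ok], yq[ok])
  matrix(v, g$n, g$n)
}

#' Collapse the detector array to a single element
#'
#' Mimics a single-element (pinhole) detector of the same overall field of
#' view by summing the maps of all active elements. The result is again an
#' `mdf_set` with one detector element, usable everywhere a full set is.
#' Applying the reduction twice is a no-op.
#'
#' @param mdf An `mdf_set`.
#' @return An `mdf_set` with `N_d = 1`.
#' @export
reduce_to_single_element <- function(mdf) {
  stopifnot(inherits(mdf, "mdf_set"))
  act <- active_elements(mdf$base$det) + 1L
  if (length(act) == 1L && mdf$base$det$n_rows == 1L && mdf$base$det$n_cols == 1L) {
    return(mdf)
  }
  summed <- rowSums(mdf$base$values[, act, drop = FALSE])
  span <- max(mdf$base$det$n_rows, mdf$base$det$n_cols) * mdf$base$det$pitch
  det1 <- detector_geometry(n_rows = 1L, n_cols = 1L, pitch = span,
                            element_size = span)
  base1 <- structure(
    list(values = matrix(summed, ncol = 1), grid = mdf$base$grid, det = det1,
         optics = mdf$base$optics),
    class = "mdf_base"
  )
  expand_orbit(base1, mdf$orbit, provenance = mdf$provenance)
}

#' Prepare a measured MDF set from raster-scan images
#'
#' Applies the post-processing used for experimentally measured detection
#' maps: an anisotropic rescale along x (to undo fast-axis stretching of the
#' galvo scan), optional smoothing (2D uniform filter followed by a Gaussian
#' blur), and the orbit expansion. Smoothing uses the EBImage package.
#'
#' @param scan_images `n x n x N_d` array (or list of matrices), one
#'   raster-scan image per detector element, `[x, y]` indexed on `grid`.
#' @param grid,det As in [simulate_base_mdf()]; the measured default pixel
#'   size is 2 nm.
#' @param orbit An [orbit_geometry()].
#' @param x_rescale Squeeze factor along x about the grid center; `0.8`
#'   shrinks features 20 % in x, `1` is the identity.
#' @param smoothing `NULL` to disable, or a list with `uniform_px` (box
#'   filter side, px) and `gaussian_px` (Gaussian sigma, px).
#' @return An `mdf_set` with `provenance = "measured"`.
#' @export
prepare_measured_mdf <- function(scan_images, grid, det, orbit,
                                 x_rescale = 0.8,
                                 smoothing = list(uniform_px = 5, gaussian_px = 2)) {
  if (is.list(scan_images)) scan_images <- simplify2array(scan_images)
  stopifnot(length(dim(scan_images)) == 3, x_rescale > 0)
  if (dim(scan_images)[1] != grid$n || dim(scan_images)[2] != grid$n) {
    stop("scan image dimensions do not match the grid")
  }
  n_el <- det$n_rows * det$n_cols
  if (dim(scan_images)[3] != n_el) {
    stop(sprintf("expected %d scan images, got %d", n_el, dim(scan_images)[3]))
  }
  out <- scan_images
  if (x_rescale != 1) {
    # out(x, y) = in(x / s, y): sample each row profile at stretched coords
    src <- grid$axis / x_rescale
    for (j in seq_len(n_el)) {
      out[, , j] <- apply(out[, , j], 2, function(col) {
        stats::approx(grid$axis, col, xout = src, rule = 2)$y
      })
    }
  }
  if (!is.null(smoothing)) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("smoothing requires the EBImage package; pass smoothing = NULL to skip")
    }
    k <- as.integer(smoothing$uniform_px %||% 0)
    gs <- smoothing$gaussian_px %||% 0
    for (j in seq_len(n_el)) {
      img <- out[, , j]
      if (k > 1) {
        box <- matrix(1 / k^2, k, k)
        img <- EBImage::filter2(img, box, boundary = "replicate")
      }
      if (gs > 0) img <- EBImage::gblur(img, sigma = gs, boundary = "replicate")
      out[, , j] <- img
    }
  }
  out[out < 0] <- 0
  base <- as_mdf_base(out, grid, det)
  # same normalization contract as the simulated path: peak total detection
  # probability (summed over elements) equals 1
  tot <- rowSums(base$values[, active_elements(det) + 1L, drop = FALSE])
  base$values <- base$values / max(tot)
  expand_orbit(base, orbit, provenance = "measured")
}

#' Write an MDF set to TIFF + JSON
#'
#' The base map stack is stored as a multi-page 32-bit float TIFF (one page
#' per detector element, ascending), and the grid, detector, orbit and
#' provenance metadata as a JSON sidecar. The orbit expansion is re-applied
#' on load, which reproduces the full set exactly.
#'
#' @param mdf An `mdf_set`.
#' @param path Output path without extension; writes `<path>.tif` and
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_mdf <- function(mdf, path) {
  stopifnot(inherits(mdf, "mdf_set"))
  g <- mdf$base$grid
  scale <- max(mdf$base$values)
  pages <- lapply(seq_len(ncol(mdf$base$values)), function(j) {
    # TIFF pages are row-major [y, x]; transpose from our [x, y] layout
    t(matrix(mdf$base$values[, j] / scale, g$n, g$n))
  })
  tiff::writeTIFF(pages, paste0(path, ".tif"), bits.per.sample = 32L)
  meta <- list(
    pixel_size = g$pixel_size, n_pixels = g$n, value_scale = scale,
    detector = unclass(mdf$base$det), orbit = unclass(mdf$orbit),
    provenance = mdf$provenance
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an MDF set written by [write_mdf()]
#'
#' @param path Path without extension.
#' @return An `mdf_set`.
#' @export
read_mdf <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  g <- mdf_grid(meta$pixel_size, meta$n_pixels)
  det <- detector_geometry(meta$detector$n_rows, meta$detector$n_cols,
                           meta$detector$pitch, meta$detector$element_size,
                           meta$detector$excluded_elements)
  orbit <- orbit_geometry(meta$orbit$L, meta$orbit$alpha0, meta$orbit$direction,
                          meta$orbit$n_positions, meta$orbit$period_ms)
  maps <- vapply(pages, function(p) t(p) * meta$value_scale,
                 matrix(0, g$n, g$n))
  base <- as_mdf_base(maps, g, det)
  expand_orbit(base, orbit, provenance = meta$provenance)
}
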