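#' 3D density maps
#'
#' A density map is a cubic-voxel intensity grid built from a localization
#' cluster: each localization increments its nearest voxel by 1, and the
#' count grid is then convolved with an isotropic Gaussian kernel whose
#' width sigma tracks the mean localization precision. Intensities are
#' stored as a 3D array `data[ix, iy, iz]` (x fastest); `origin` is the
#' world coordinate (nm) of the centre of voxel `[1, 1, 1]`.
#'
#' @param data 3D numeric array of non-negative intensities.
#' @param origin numeric length-3, nm.
#' @param voxel voxel edge length, nm (> 0).
#' @param sigma kernel width used to build the map, nm (or NA).
#' @param threshold iso-contour threshold (or NA until set).
#' @return an object of class `density_map`.
#' @export
density_map <- function(data, origin, voxel, sigma = NA_real_,
                        threshold = NA_real_) {
  if (length(dim(data)) != 3L) stop_ct("data must be a 3D array")
  if (any(dim(data) < 1L)) stop_ct("grid dimensions must be >= 1 per axis")
  if (voxel <= 0) stop_ct("voxel size must be > 0")
  if (any(data < 0)) stop_ct("intensities must be non-negative")
  if (!is.na(threshold) &&
      (threshold < min(data) || threshold > max(data)))
    stop_ct("threshold must lie within the intensity range")
  structure(list(data = data, origin = as.numeric(origin),
                 voxel = as.numeric(voxel), sigma = as.numeric(sigma),
                 threshold = as.numeric(threshold)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("density_map: %d x %d x %d voxels @ %g nm", d[1], d[2], d[3],
              x$voxel), "\n")
  cat(sprintf("  origin (%g, %g, %g) nm; sigma %s nm; threshold %s\n",
              x$origin[1], x$origin[2], x$origin[3],
              format(x$sigma), format(x$threshold)))
  cat(sprintf("  total intensity %.4g; max %.4g\n", sum(x$data), max(x$data)))
  invisible(x)
}

# World coordinates (nm) of all voxel centres, or of a logical/index subset.
voxel_centers <- function(map, which = NULL) {
  d <- dim(map$data)
  if (is.null(which)) which <- seq_len(prod(d))
  if (is.logical(which)) which <- which(which)
  idx <- arrayInd(which, d)
  sweep((idx - 1) * map$voxel, 2, map$origin, "+")
}

# Logical mask of above-threshold voxels ("the body").
body_mask <- function(map) {
  thr <- map$threshold
  if (is.na(thr)) stop_ct("map has no iso-contour threshold set")
  map$data >= thr
}

#' Rasterize a localization cluster onto a count grid
#'
#' Builds the integer count grid underlying a density map: for each
#' localization the count of its nearest voxel is increased by 1, so the
#' grid total equals the number of localizations.
#'
#' @param cluster a localization table (or data frame with `x_nm, y_nm,
#'   z_nm`) holding the cluster members.
#' @param voxel_size voxel edge length, nm (default 25).
#' @param padding margin added around the cluster bounding box, nm.
#' @return a `density_map` whose `data` holds integer counts (sigma NA).
#' @export
rasterize <- function(cluster, voxel_size = 25, padding = 0) {
  pts <- as.matrix(as.data.frame(cluster)[, c("x_nm", "y_nm", "z_nm")])
  if (!nrow(pts)) stop_ct("cannot rasterize an empty cluster")
  if (voxel_size <= 0) stop_ct("voxel_size must be > 0")
  lo <- apply(pts, 2, min) - padding
  hi <- apply(pts, 2, max) + padding
  origin <- lo
  d <- pmax(floor((hi - origin) / voxel_size + 0.5) + 1L, 1L)
  idx <- sweep(pts, 2, origin)
  idx <- pmin(pmax(round(idx / voxel_size) + 1L, 1L),
              matrix(d, nrow(pts), 3, byrow = TRUE))
  arr <- array(0, dim = d)
  lin <- (idx[, 3] - 1L) * d[1] * d[2] + (idx[, 2] - 1L) * d[1] + idx[, 1]
  tab <- tabulate(lin, nbins = prod(d))
  arr[] <- tab
  density_map(arr, origin, voxel_size)
}

#' Convolve a count grid with an isotropic Gaussian kernel
#'
#' Separable convolution along each axis with a discrete Gaussian of width
#' `sigma` (nm), truncated at 4 sigma and normalised to unit mass, so the
#' total intensity is conserved up to boundary truncation.
#'
#' @param map a `density_map` (typically counts from [rasterize()]).
#' @param sigma kernel width, nm (> 0).
#' @return the smoothed `density_map` with `sigma` recorded.
#' @export
convolve_gaussian <- function(map, sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop_ct("sigma must be > 0")
  rad <- ceiling(4 * sigma / map$voxel)
  off <- (-rad):rad
  k <- exp(-(off * map$voxel)^2 / (2 * sigma^2))
  k <- k / sum(k)

  arr <- map$data
  d <- dim(arr)
  # band matrix for 1D convolution along an axis of length n
  band <- function(n) {
    K <- matrix(0, n, n)
    for (j in seq_len(n)) {
      i <- j + off
      ok <- i >= 1 & i <= n
      K[cbind(i[ok], j)] <- K[cbind(i[ok], j)] + k[ok]
    }
    K
  }
  # axis 1 (x)
  dim(arr) <- c(d[1], d[2] * d[3])
  arr <- band(d[1]) %*% arr
  dim(arr) <- d
  # axis 2 (y)
  arr <- aperm(arr, c(2, 1, 3))
  da <- dim(arr)
  dim(arr) <- c(da[1], da[2] * da[3])
  arr <- band(d[2]) %*% arr
  dim(arr) <- da
  arr <- aperm(arr, c(2, 1, 3))
  # axis 3 (z)
  arr <- aperm(arr, c(3, 2, 1))
  da <- dim(arr)
  dim(arr) <- c(da[1], da[2] * da[3])
  arr <- band(d[3]) %*% arr
  dim(arr) <- da
  arr <- aperm(arr, c(3, 2, 1))
  arr[arr < 0] <- 0  # numerical negatives from BLAS rounding

  density_map(arr, map$origin, map$voxel, sigma = sigma,
              threshold = map$threshold)
}

#' Build a density map from a localization cluster
#'
#' Convenience chain: [rasterize()] then [convolve_gaussian()] then
#' [iso_threshold()]. When `sigma = "auto"` the kernel width is the mean of
#' the cluster's lateral and axial precisions (proportionality constant 1).
#'
#' @param cluster localization table of cluster members.
#' @param voxel_size voxel edge, nm (default 25).
#' @param sigma kernel width in nm, or `"auto"`.
#' @param padding grid margin, nm; default `5 * sigma`.
#' @param grid optional template `density_map` whose frame (origin, dims,
#'   voxel) the new map must share; used to build several segment maps on a
#'   common nucleus-wide grid.
#' @return a thresholded `density_map`.
#' @export
build_density_map <- function(cluster, voxel_size = 25, sigma = "auto",
                              padding = NULL, grid = NULL) {
  df <- as.data.frame(cluster)
  if (identical(sigma, "auto")) {
    if (!all(c("lat_prec_nm", "ax_prec_nm") %in% names(df)))
      stop_ct("sigma = 'auto' needs lat_prec_nm and ax_prec_nm columns")
    sigma <- mean(c(df$lat_prec_nm, df$ax_prec_nm))
  }
  if (is.null(grid)) {
    padding <- padding %||% (5 * sigma)
    counts <- rasterize(df, voxel_size, padding)
  } else {
    counts <- rasterize_on_grid(df, grid)
  }
  m <- convolve_gaussian(counts, sigma)
  thr <- tryCatch(iso_threshold(m), error = function(e) NA_real_)
  if (!is.na(thr)) {
    m <- shift_background(m)
  } else {
    # zero-background limit: the body is every positive voxel
    pos <- m$data[m$data > 0]
    m$threshold <- if (length(pos)) min(pos) else 0
  }
  m
}

# Rasterize onto an existing grid frame (counts outside are clipped to the
# nearest edge voxel, matching rasterize()'s clamping).
rasterize_on_grid <- function(cluster, grid) {
  pts <- as.matrix(as.data.frame(cluster)[, c("x_nm", "y_nm", "z_nm")])
  if (!nrow(pts)) stop_ct("cannot rasterize an empty cluster")
  d <- dim(grid$data)
  idx <- sweep(pts, 2, grid$origin)
  idx <- pmin(pmax(round(idx / grid$voxel) + 1L, 1L),
              matrix(d, nrow(pts), 3, byrow = TRUE))
  arr <- array(0, dim = d)
  lin <- (idx[, 3] - 1L) * d[1] * d[2] + (idx[, 2] - 1L) * d[1] + idx[, 1]
  arr[] <- tabulate(lin, nbins = prod(d))
  density_map(arr, grid$origin, grid$voxel)
}

#' Iso-contour threshold from the background peak
#'
#' Locates the background mode of the voxel-intensity histogram
#' (Freedman–Diaconis bins; the mode is the tallest bin centre), conceptually
#' shifts all intensities so the mode sits at zero, and returns one standard
#' deviation of the background (sub-mode) population on that shifted scale:
#' `sqrt(mean((x - mode)^2))` over voxels with `x <= mode`. By construction
#' the result is invariant to adding a constant offset to the map.
#'
#' @param map a `density_map` with at least 2 distinct intensity values.
#' @return the scalar threshold (attribute `"mode"` carries the background
#'   mode on the original scale).
#' @export
iso_threshold <- function(map) {
  v <- as.numeric(map$data)
  if (length(unique(v)) < 2L)
    stop_ct("constant map: background histogram is degenerate")
  iqr <- stats::IQR(v)
  bw <- if (iqr > 0) 2 * iqr / length(v)^(1 / 3) else
    diff(range(v)) / ceiling(sqrt(length(v)))
  # cap the bin count: near-constant backgrounds give vanishing IQR and
  # would otherwise request astronomically many breaks
  nbins <- min(ceiling(diff(range(v)) / bw), 4096)
  bw <- diff(range(v)) / nbins
  breaks <- seq(min(v), max(v) + bw, by = bw)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  mode <- h$mids[which.max(h$counts)]
  bg <- v[v <= mode]
  thr <- sqrt(mean((bg - mode)^2))
  attr(thr, "mode") <- mode
  thr
}

#' Shift the background peak to zero and set the one-sigma threshold
#'
#' Applies [iso_threshold()]: intensities are shifted so the background mode
#' sits at zero (clipped at zero from below) and the map's `threshold` field
#' is set to one background sigma.
#'
#' @param map a `density_map`.
#' @return the shifted, thresholded map.
#' @export
shift_background <- function(map) {
  thr <- iso_threshold(map)
  mode <- attr(thr, "mode")
  arr <- map$data - mode
  arr[arr < 0] <- 0
  density_map(arr, map$origin, map$voxel, sigma = map$sigma,
              threshold = min(as.numeric(thr), max(arr)))
}

# Block-average a map by an integer factor (used for coarse search grids).
downsample_map <- function(map, factor = 2L) {
  d <- dim(map$data)
  dn <- pmax(d %/% factor, 1L)
  arr <- array(0, dim = dn)
  cnt <- array(0, dim = dn)
  idx <- arrayInd(seq_len(prod(d)), d)
  tgt <- pmin((idx - 1L) %/% factor + 1L,
              matrix(dn, nrow(idx), 3, byrow = TRUE))
  lin <- (tgt[, 3] - 1L) * dn[1] * dn[2] + (tgt[, 2] - 1L) * dn[1] + tgt[, 1]
  sums <- tabulate(lin, nbins = prod(dn))
  vals <- rowsum(as.numeric(map$data), lin)
  arr[as.integer(rownames(vals))] <- vals / pmax(sums[as.integer(rownames(vals))], 1)
  density_map(arr, map$origin + (factor - 1) * map$voxel / 2,
              map$voxel * factor, sigma = map$sigma,
              threshold = NA_real_)
}

#' Body volume within the iso-contour threshold
#'
#' The number of voxels at or above the threshold times the voxel volume.
#'
#' @param map a thresholded `density_map`.
#' @return volume in nm^3 (0 when no voxel passes).
#' @export
body_volume <- function(map) {
  sum(body_mask(map)) * map$voxel^3
}

#' Convex-hull surface area of the map body
#'
#' Area of the convex hull of the above-threshold voxel centres, summed over
#' the hull's surface triangles.
#'
#' @param map a thresholded `density_map`.
#' @return area in nm^2.
#' @export
surface_area <- function(map) {
  pts <- voxel_centers(map, body_mask(map))
  convex_hull_area(pts)
}

#' Sphericity of a body
#'
#' `psi = pi^(1/3) * (6 V)^(2/3) / A`: 1 for a perfect sphere, smaller for
#' irregular bodies.
#'
#' @param volume body volume (nm^3, > 0).
#' @param area body surface area (nm^2, > 0).
#' @return the dimensionless sphericity.
#' @export
sphericity <- function(volume, area) {
  if (any(volume <= 0) || any(area <= 0))
    stop_ct("volume and area must be > 0")
  pi^(1 / 3) * (6 * volume)^(2 / 3) / area
}
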