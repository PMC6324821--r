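# Pairwise and per-segment structural statistics on density maps.

# Intensity-weighted centre of mass of the above-threshold body (nm).
map_com <- function(map) {
  mask <- body_mask(map)
  if (!any(mask)) stop_ct("map has an empty body above threshold")
  w <- map$data[mask]
  ctr <- voxel_centers(map, mask)
  colSums(ctr * w) / sum(w)
}

#' Distance score (DS) between two density maps
#'
#' Euclidean distance (nm) between the intensity-weighted centres of mass
#' of the two maps' above-threshold bodies.
#'
#' @param mapA,mapB thresholded `density_map` objects.
#' @return distance in nm.
#' @export
distance_score <- function(mapA, mapB) {
  sqrt(sum((map_com(mapA) - map_com(mapB))^2))
}

#' Entanglement score (ES) between two density maps
#'
#' Fraction of overlapping above-threshold voxels relative to the smaller
#' of the two bodies. Maps need not share a grid frame: body voxels of A are
#' mapped into B's grid by rounding their world coordinates, so any common
#' region is counted once per A voxel.
#'
#' @param mapA,mapB thresholded `density_map` objects.
#' @return overlap fraction in `[0, 1]`; 1 iff the smaller body is contained
#'   in the larger.
#' @export
entanglement_score <- function(mapA, mapB) {
  mA <- body_mask(mapA); mB <- body_mask(mapB)
  nA <- sum(mA); nB <- sum(mB)
  if (!nA || !nB) stop_ct("both maps must have non-empty bodies")
  # count A-body voxels whose centre falls in a B-body voxel
  ctrA <- voxel_centers(mapA, mA)
  dB <- dim(mapB$data)
  idx <- round(sweep(ctrA, 2, mapB$origin) / mapB$voxel) + 1
  ok <- idx[, 1] >= 1 & idx[, 1] <= dB[1] & idx[, 2] >= 1 &
    idx[, 2] <= dB[2] & idx[, 3] >= 1 & idx[, 3] <= dB[3]
  inter <- 0L
  if (any(ok)) {
    lin <- (idx[ok, 3] - 1) * dB[1] * dB[2] + (idx[ok, 2] - 1) * dB[1] +
      idx[ok, 1]
    inter <- sum(mB[lin])
  }
  min(inter / min(nA, nB), 1)
}

#' Power-law fit `value = a * size^b`
#'
#' Ordinary least squares in log–log space; the residual standard deviation
#' `s_res` is computed on the linear scale (observed minus expected), the
#' scale on which size-corrected z-scores are expressed.
#'
#' @param values positive response values.
#' @param sizes positive genomic sizes/separations (bp).
#' @return an object of class `power_law_fit` with `a`, `b`, `s_res`.
#' @export
power_law_fit <- function(values, sizes) {
  keep <- is.finite(values) & is.finite(sizes) & values > 0 & sizes > 0
  if (sum(keep) < 3L) stop_ct("power-law fit needs >= 3 positive points")
  fit <- lm(log(values[keep]) ~ log(sizes[keep]))
  a <- exp(coef(fit)[[1]])
  b <- coef(fit)[[2]]
  expected <- a * sizes[keep]^b
  s_res <- sqrt(mean((values[keep] - expected)^2))
  structure(list(a = a, b = b, s_res = s_res), class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law fit: value = %.4g * size^%.4g (s_res = %.4g)\n",
              x$a, x$b, x$s_res))
  invisible(x)
}

#' Size-corrected z-scores against a power-law expectation
#'
#' Expresses each value relative to its genomic-size expectation:
#' `z = (observed - a * size^b) / s_res`. The fit is estimated from the data
#' by [power_law_fit()] unless supplied. Applied identically to distance
#' scores (against genomic separation) and to entanglement, area, volume
#' and sphericity (against segment genomic size).
#'
#' @param values observed values (>= 0; zeros are allowed and scored against
#'   the fitted expectation, but only positive values enter the fit).
#' @param sizes genomic sizes or separations (bp, > 0).
#' @param fit an optional pre-computed `power_law_fit`.
#' @return numeric z-scores; the fit is attached as attribute `"fit"`.
#' @export
size_corrected_zscore <- function(values, sizes, fit = NULL) {
  if (length(values) != length(sizes))
    stop_ct("values and sizes must have equal length")
  if (any(sizes <= 0) || any(values < 0))
    stop_ct("sizes must be > 0 and values >= 0")
  if (is.null(fit)) fit <- power_law_fit(values, sizes)
  expected <- fit$a * sizes^fit$b
  if (fit$s_res <= 1e-12 * mean(abs(values))) {
    # exact fit: all points sit on the curve, all z-scores vanish
    z <- rep(0, length(values))
  } else {
    z <- (values - expected) / fit$s_res
  }
  attr(z, "fit") <- fit
  z
}

#' Average spatial overlap of two localization clusters
#'
#' Builds an occupancy body for each cluster — the union of balls of radius
#' `alpha` around its points, sampled on a cubic voxel grid (a grid proxy
#' for the alpha-shape surface) — and returns the mean of the two directed
#' containment fractions `|A&B|/|A|` and `|A&B|/|B|`. With `align = TRUE`
#' the second cluster is first translated so its centre of mass matches the
#' first (the aligned-overlap variant).
#'
#' @param clusterA,clusterB localization tables (or data frames with
#'   `x_nm, y_nm, z_nm`).
#' @param alpha body radius in nm (default 150, the DBSCAN reach).
#' @param voxel grid step for the occupancy proxy (nm).
#' @param align translate B's centre of mass onto A's first?
#' @return the average overlap fraction in `[0, 1]`.
#' @export
spatial_overlap <- function(clusterA, clusterB, alpha = 150, voxel = 25,
                            align = FALSE) {
  if (alpha <= 0) stop_ct("alpha must be > 0")
  A <- as.matrix(as.data.frame(clusterA)[, c("x_nm", "y_nm", "z_nm")])
  B <- as.matrix(as.data.frame(clusterB)[, c("x_nm", "y_nm", "z_nm")])
  if (!nrow(A) || !nrow(B)) stop_ct("clusters must be non-empty")
  if (align) B <- sweep(B, 2, colMeans(B) - colMeans(A))

  lo <- pmin(apply(A, 2, min), apply(B, 2, min)) - alpha - voxel
  hi <- pmax(apply(A, 2, max), apply(B, 2, max)) + alpha + voxel
  d <- as.integer(floor((hi - lo) / voxel) + 1L)

  occupancy <- function(P) {
    # voxels whose centre lies within alpha of any point
    rad <- ceiling(alpha / voxel)
    offs <- as.matrix(expand.grid(-rad:rad, -rad:rad, -rad:rad))
    offs <- offs[rowSums((offs * voxel)^2) <= (alpha + voxel / 2)^2, ,
                 drop = FALSE]
    occ <- logical(prod(d))
    ctr <- round(sweep(P, 2, lo) / voxel)
    for (i in seq_len(nrow(P))) {
      v <- sweep(offs, 2, as.numeric(ctr[i, ]), "+")
      ok <- v[, 1] >= 0 & v[, 1] < d[1] & v[, 2] >= 0 & v[, 2] < d[2] &
        v[, 3] >= 0 & v[, 3] < d[3]
      occ[v[ok, 3] * d[1] * d[2] + v[ok, 2] * d[1] + v[ok, 1] + 1L] <- TRUE
    }
    occ
  }
  oA <- occupancy(A)
  oB <- occupancy(B)
  inter <- sum(oA & oB)
  mean(c(inter / sum(oA), inter / sum(oB)))
}
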