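# Shared fixture builders (all generated in code; no stored data).

# Localization table from a coordinate matrix, with well-behaved metrics.
locs_from_points <- function(pts, frame = seq_len(nrow(pts)), round = 1L,
                             lat = 11, ax = 47) {
  localizations(pts[, 1], pts[, 2], pts[, 3], frame = frame,
                psf_photons = 1000, cutout_photons = 1500, z_offset_nm = 0,
                lat_prec_nm = lat, ax_prec_nm = ax, round = round)
}

# Gaussian blob of n points at a centre.
blob <- function(n, center = c(0, 0, 0), sd = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sweep(matrix(rnorm(3 * n, sd = sd), n, 3), 2, center, "+")
}

# Density map with a single Gaussian blob (for CCC / COM tests).
blob_map <- function(n = 64, voxel = 10, sigma = 30, center = NULL,
                     seed = 1) {
  set.seed(seed)
  center <- center %||% rep((n - 1) * voxel / 2, 3)
  pts <- sweep(matrix(rnorm(600, sd = 60), 200, 3), 2, center, "+")
  cl <- data.frame(x_nm = pts[, 1], y_nm = pts[, 2], z_nm = pts[, 3])
  g <- density_map(array(0, dim = c(n, n, n)), c(0, 0, 0), voxel)
  m <- convolve_gaussian(chromotrace:::rasterize_on_grid(cl, g), sigma)
  m$threshold <- iso_threshold(m)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force O(n^2) DBSCAN oracle: distance-matrix density reachability
# with the same deterministic border rule (nearest core, lowest index).
dbscan_oracle <- function(pts, eps, min_points) {
  n <- nrow(pts)
  D <- as.matrix(dist(pts))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  is_core <- vapply(nb, length, integer(1)) >= min_points
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is_core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    members <- i
    labels[i] <- cl
    repeat {
      grow <- unique(unlist(nb[members]))
      grow <- grow[is_core[grow] & labels[grow] == 0L]
      if (!length(grow)) break
      labels[grow] <- cl
      members <- grow
    }
  }
  for (i in seq_len(n)) {
    if (is_core[i] || labels[i] != 0L) next
    cores <- nb[[i]][is_core[nb[[i]]]]
    if (length(cores)) labels[i] <- labels[cores[which.min(D[i, cores])]]
  }
  if (cl > 0L) {
    sizes <- tabulate(labels, nbins = cl)
    first <- vapply(seq_len(cl), function(k) min(which(labels == k)),
                    integer(1))
    relab <- integer(cl)
    relab[order(-sizes, first)] <- seq_len(cl)
    labels[labels > 0L] <- relab[labels[labels > 0L]]
  }
  labels
}

# Small planted restraint toy: straight-ish chain with one enforced contact.
toy_restraints <- function(n = 10, r = 15) {
  m <- diag(1, n)
  for (d in 1:(n - 1)) for (i in 1:(n - d)) m[i, i + d] <- m[i + d, i] <- 1 / d
  restraints_from_contacts(m, bead_radius = r)
}
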