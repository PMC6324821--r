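# Rigid-body fitting of bead models into density maps: CCC scoring,
# interface centre of mass, connectivity score, and the 100-placement
# random-search + steepest-ascent protocol.

#' Cross-correlation coefficient between two density maps
#'
#' Pearson-form correlation over all voxels of the common grid:
#' `sum((rhoP - mean) (rhoT - mean)) / sqrt(sum(..^2) sum(..^2))`. The raw
#' value can be negative; for scoring it is floored at 0 (the reported
#' 0-to-1 range), with the raw value kept in diagnostics.
#'
#' @param mapP,mapT `density_map`s on the same grid (or plain numeric
#'   arrays/vectors of equal length).
#' @return the raw CCC.
#' @export
ccc <- function(mapP, mapT) {
  a <- if (inherits(mapP, "density_map")) as.numeric(mapP$data) else as.numeric(mapP)
  b <- if (inherits(mapT, "density_map")) as.numeric(mapT$data) else as.numeric(mapT)
  if (length(a) != length(b)) stop_ct("maps must share a grid")
  v <- cpp_pearson(a, b)
  if (is.na(v)) stop_ct("zero-variance map: CCC undefined")
  v
}

#' Render a bead model as a probe density map on a target grid
#'
#' Beads are rasterized with weight 1 and convolved with the target map's
#' kernel sigma, so probe and target intensities are commensurate.
#'
#' @param coords bead coordinates (n x 3, nm) or a `bead_model`.
#' @param map the target `density_map` supplying grid frame and sigma.
#' @param sigma kernel override (nm).
#' @return a `density_map` on `map`'s grid.
#' @export
render_model <- function(coords, map, sigma = NULL) {
  if (inherits(coords, "bead_model")) coords <- coords$coords
  sigma <- sigma %||% map$sigma
  if (is.na(sigma)) stop_ct("target map has no sigma; supply one")
  g <- cpp_splat_gaussian(as.matrix(coords), rep(1, nrow(coords)),
                          dim(map$data), map$origin, map$voxel, sigma)
  density_map(array(g, dim(map$data)), map$origin, map$voxel, sigma = sigma)
}

#' Interface centre of mass between two density-map bodies
#'
#' Intensity-weighted centre of mass of the A-body voxels lying within
#' `cutoff` nm of any B-body voxel. When the bodies are farther apart than
#' the cutoff there is no interface: the function returns `NULL` (a
#' recorded no-interface signal, not an error).
#'
#' @param mapA,mapB thresholded `density_map`s.
#' @param cutoff interface distance in nm (default 50).
#' @return the interface centre of mass (length-3, nm), or `NULL`.
#' @export
interface_com <- function(mapA, mapB, cutoff = 50) {
  if (cutoff <= 0) stop_ct("cutoff must be > 0")
  mA <- body_mask(mapA); mB <- body_mask(mapB)
  if (!any(mA) || !any(mB)) stop_ct("both bodies must be non-empty")
  ctrA <- voxel_centers(mapA, mA)
  ctrB <- voxel_centers(mapB, mB)
  d <- cpp_min_dist(ctrA, ctrB)
  sel <- d <= cutoff
  if (!any(sel)) return(NULL)
  w <- mapA$data[mA][sel]
  colSums(ctrA[sel, , drop = FALSE] * w) / sum(w)
}

#' Connectivity score from endpoint-to-interface distances
#'
#' `ConS_i = 1 - d_i / max_j(d_j)` over the ensemble of candidate fits,
#' where `d_i` is the distance between the fit's terminal bead (the one
#' genomically adjacent to the neighbouring segment) and the interface
#' centre of mass. The fit attaining the maximal distance scores 0; in a
#' single-member ensemble that is the only member. All-zero distances give
#' the degenerate all-1 score (flagged with a warning).
#'
#' @param d_values non-negative endpoint-to-interface distances (nm).
#' @return ConS per fit, in `[0, 1]`.
#' @export
connectivity_score <- function(d_values) {
  if (!length(d_values)) stop_ct("need >= 1 distance")
  if (any(d_values < 0)) stop_ct("distances must be >= 0")
  mx <- max(d_values)
  if (mx == 0) {
    warning("all endpoint distances are zero; ConS degenerate at 1")
    return(rep(1, length(d_values)))
  }
  1 - d_values / mx
}

# Rotation matrix from an axis-angle vector (Rodrigues).
rotation_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Uniform random rotation matrix (via random unit quaternion).
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# Apply a pose (rotation about the model centroid + translation of the
# centroid) to centred coordinates.
apply_pose <- function(centered, pose_rot, center_at) {
  sweep(centered %*% t(pose_rot), 2, center_at, "+")
}

#' Rigid fitting of a bead model into a density map
#'
#' Generates `n_placements` random placements (uniform rotation, centroid
#' translated uniformly within the map bounding box), locally optimizes
#' each pose by steepest ascent on the CCC between the rendered probe map
#' and the target (central-difference gradient over the 6 pose parameters,
#' step-halving line search, stop at `dccc_tol` or `max_iter`), and scores
#' every fit with CCC, ConS and `CombScore = ConS + 2 * CCC`. Fits at or
#' above the 95th percentile of CombScore are flagged for refinement.
#'
#' Without a neighbour interface (`interface = NULL`) the connectivity term
#' is undefined; ConS is recorded as 0 for all fits and CombScore reduces
#' to `2 * CCC` (flagged in the result).
#'
#' @param model a `bead_model`.
#' @param map the target `density_map` (thresholded, with sigma).
#' @param n_placements random placements (default 100).
#' @param seed RNG seed.
#' @param interface interface centre of mass from [interface_com()] (or
#'   NULL).
#' @param terminal which terminal bead is genomically adjacent to the
#'   neighbour segment: `"first"` or `"last"`.
#' @param percentile CombScore percentile for refinement flagging
#'   (default 0.95).
#' @param max_iter,dccc_tol steepest-ascent controls.
#' @return an object of class `rigid_fit_ensemble`: data frame `fits`
#'   (placement, ccc_raw, ccc, d_com, cons, comb_score, refine), list
#'   `poses` (rotation + translation per placement), `coords` of the best
#'   fit, and `best` (index).
#' @export
rigid_fit <- function(model, map, n_placements = 100, seed = NULL,
                      interface = NULL, terminal = c("last", "first"),
                      percentile = 0.95, max_iter = 200, dccc_tol = 1e-4) {
  terminal <- match.arg(terminal)
  if (n_placements < 1) stop_ct("n_placements must be >= 1")
  X <- model$coords
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  d <- dim(map$data)
  lo <- map$origin
  hi <- map$origin + (d - 1) * map$voxel
  if (max(dist(rbind(apply(X, 2, min), apply(X, 2, max)))) >
      3 * max(hi - lo))
    warning("model diameter exceeds 3x the map extent; check scales")
  target <- as.numeric(map$data)
  sigma <- map$sigma
  if (is.na(sigma)) stop_ct("map must carry a kernel sigma")

  # coarse-to-fine ascent: a first pass against the map smoothed to twice
  # the kernel width widens the attraction basins (rotation landscapes of
  # coil-like chains are rugged at native resolution), then the pose is
  # polished at native resolution
  sigma_coarse <- 2 * sigma
  map_coarse <- downsample_map(
    convolve_gaussian(map, sqrt(sigma_coarse^2 - sigma^2)), 2L)
  target_coarse <- as.numeric(map_coarse$data)

  eval_ccc <- function(R, t, coarse = FALSE) {
    if (coarse)
      cpp_render_ccc(apply_pose(Xc, R, t), target_coarse,
                     dim(map_coarse$data), map_coarse$origin,
                     map_coarse$voxel, sigma_coarse, truncate = 3)
    else
      cpp_render_ccc(apply_pose(Xc, R, t), target, dim(map$data),
                     map$origin, map$voxel, sigma, truncate = 4)
  }

  # radius of gyration: converts rotation angles to effective displacements
  # so all 6 pose parameters live on a common nm scale
  rg <- sqrt(mean(rowSums(Xc^2)))

  # steepest ascent on the analytic pose gradient, re-parametrizing the
  # rotation at every step (axis-angle increments about the current pose,
  # where the rotation Jacobian is exact); adaptive step with halving
  ascend <- function(R, t, coarse, maxit) {
    if (coarse) {
      tgt <- target_coarse; dm <- dim(map_coarse$data)
      org <- map_coarse$origin; vx <- map_coarse$voxel
      sg <- sigma_coarse; tr <- 3
    } else {
      tgt <- target; dm <- dim(map$data); org <- map$origin
      vx <- map$voxel; sg <- sigma; tr <- 4
    }
    step <- 2 * vx
    pg <- cpp_pose_ccc_grad(Xc, R, t, tgt, dm, org, vx, sg, tr)
    cur <- if (is.na(pg$ccc)) -1 else pg$ccc
    for (it in seq_len(maxit)) {
      g <- pg$grad
      g[4:6] <- g[4:6] / rg          # rad -> common nm scale
      gn <- sqrt(sum(g^2))
      if (!is.finite(gn) || gn < 1e-14) break
      g <- g / gn
      improved <- FALSE
      repeat {
        Rn <- rotation_matrix(step * g[4:6] / rg) %*% R
        tn <- t + step * g[1:3]
        v <- cpp_render_ccc(apply_pose(Xc, Rn, tn), tgt, dm, org, vx, sg,
                            tr)
        if (!is.na(v) && v > cur) {
          delta <- v - cur
          R <- Rn; t <- tn; cur <- v
          improved <- TRUE
          step <- step * 1.4
          if (delta < dccc_tol) return(list(R = R, t = t, ccc = cur))
          break
        }
        step <- step / 2
        if (step < vx / 64) break
      }
      if (!improved) break
      pg <- cpp_pose_ccc_grad(Xc, R, t, tgt, dm, org, vx, sg, tr)
    }
    list(R = R, t = t, ccc = cur)
  }
  optimize_pose <- function(R0, t0) {
    s1 <- ascend(R0, t0, coarse = TRUE, maxit = max_iter)
    s2 <- ascend(s1$R, s1$t, coarse = FALSE, maxit = max_iter)
    # score at the native render used everywhere else; a probe entirely
    # outside the grid has zero variance and scores -1 (floored later)
    v <- eval_ccc(s2$R, s2$t)
    s2$ccc <- if (is.na(v)) -1 else v
    s2
  }

  res <- with_seed(seed, lapply(seq_len(n_placements), function(p) {
    R0 <- random_rotation()
    t0 <- lo + runif(3) * (hi - lo)
    optimize_pose(R0, t0)
  }))

  ccc_raw <- vapply(res, function(r) r$ccc, numeric(1))
  ccc_flr <- pmax(ccc_raw, 0)

  d_com <- rep(NA_real_, n_placements)
  if (!is.null(interface)) {
    for (p in seq_len(n_placements)) {
      coords <- apply_pose(Xc, res[[p]]$R, res[[p]]$t)
      endp <- if (terminal == "last") coords[nrow(coords), ] else coords[1, ]
      d_com[p] <- sqrt(sum((endp - interface)^2))
    }
    cons <- connectivity_score(d_com)
  } else {
    cons <- rep(0, n_placements)
  }
  comb <- cons + 2 * ccc_flr
  thr <- quantile(comb, percentile, names = FALSE)
  fits <- data.frame(placement = seq_len(n_placements), ccc_raw = ccc_raw,
                     ccc = ccc_flr, d_com = d_com, cons = cons,
                     comb_score = comb, refine = comb >= thr)
  best <- which.max(comb)
  structure(list(fits = fits,
                 poses = lapply(res, function(r) list(R = r$R, t = r$t)),
                 coords = apply_pose(Xc, res[[best]]$R, res[[best]]$t),
                 best = best, has_interface = !is.null(interface),
                 model = model, map_dim = dim(map$data)),
            class = "rigid_fit_ensemble")
}

#' @export
print.rigid_fit_ensemble <- function(x, ...) {
  b <- x$fits[x$best, ]
  cat(sprintf("rigid_fit_ensemble: %d placements; best CCC %.3f, ConS %s, CombScore %.3f\n",
              nrow(x$fits), b$ccc,
              if (x$has_interface) sprintf("%.3f", b$cons) else "n/a",
              b$comb_score))
  cat(sprintf("  %d fit(s) flagged for refinement (>= 95th percentile)\n",
              sum(x$fits$refine)))
  invisible(x)
}

#' @export
summary.rigid_fit_ensemble <- function(object, ...) {
  s <- summary(object$fits$ccc)
  print(object)
  cat("  CCC distribution:\n")
  print(s)
  invisible(object$fits)
}
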