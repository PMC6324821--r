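# Incremental (beneath-beyond) 3D convex hull.
#
# Standard computational-geometry primitive, implemented here because no
# installed package provides a 3D hull. Points are processed incrementally;
# faces visible from a new point are removed and the horizon is re-triangulated.

#' 3D convex hull of a point cloud
#'
#' @param pts numeric matrix (n x 3).
#' @return a list with `faces` (m x 3 vertex indices, outward-oriented),
#'   `area` (total surface area) and `volume` (enclosed volume).
#' @export
convex_hull_3d <- function(pts) {
  pts <- as.matrix(pts)
  if (ncol(pts) != 3L) stop_ct("pts must have 3 columns")
  n <- nrow(pts)
  if (n < 4L) stop_ct("convex hull needs >= 4 points")
  scale <- max(apply(pts, 2, function(v) diff(range(v))))
  if (scale <= 0) stop_ct("degenerate (coincident) points")
  tol <- 1e-9 * scale

  # --- initial tetrahedron from well-spread points
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) { i1 <- which.min(pts[, 2]); i2 <- which.max(pts[, 2]) }
  v12 <- pts[i2, ] - pts[i1, ]
  d_line <- apply(pts, 1, function(p) {
    w <- p - pts[i1, ]
    sqrt(max(sum(w * w) - sum(w * v12)^2 / sum(v12 * v12), 0))
  })
  i3 <- which.max(d_line)
  if (d_line[i3] < tol) stop_ct("degenerate (collinear) points")
  nrm <- cross3(v12, pts[i3, ] - pts[i1, ])
  d_plane <- abs(as.numeric((pts - matrix(pts[i1, ], n, 3, byrow = TRUE)) %*%
                              nrm)) / sqrt(sum(nrm * nrm))
  i4 <- which.max(d_plane)
  if (d_plane[i4] < tol) stop_ct("degenerate (coplanar) points")

  centroid <- colMeans(pts[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- t(apply(faces, 1, orient_face, pts = pts, interior = centroid))
  normals <- t(apply(faces, 1, face_normal, pts = pts))

  alive <- rep(TRUE, nrow(faces))
  for (p in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    live <- which(alive)
    vis <- live[vapply(live, function(f)
      sum(normals[f, ] * (pts[p, ] - pts[faces[f, 1], ])) > tol,
      logical(1))]
    if (!length(vis)) next
    # horizon: edges bounding exactly one visible face
    edges <- do.call(rbind, lapply(vis, function(f) {
      v <- faces[f, ]
      rbind(sort(c(v[1], v[2])), sort(c(v[2], v[3])), sort(c(v[1], v[3])))
    }))
    key <- paste(edges[, 1], edges[, 2])
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    alive[vis] <- FALSE
    for (e in seq_len(nrow(horizon))) {
      nf <- orient_face(c(horizon[e, ], p), pts, centroid)
      faces <- rbind(faces, nf)
      normals <- rbind(normals, face_normal(nf, pts))
      alive <- c(alive, TRUE)
    }
  }
  faces <- faces[alive, , drop = FALSE]
  tri_area <- apply(faces, 1, function(f)
    0.5 * sqrt(sum(cross3(pts[f[2], ] - pts[f[1], ],
                          pts[f[3], ] - pts[f[1], ])^2)))
  # signed tetra volumes against the centroid (outward orientation)
  tri_vol <- apply(faces, 1, function(f) {
    a <- pts[f[1], ] - centroid; b <- pts[f[2], ] - centroid
    c <- pts[f[3], ] - centroid
    sum(a * cross3(b, c)) / 6
  })
  list(faces = unname(faces), area = sum(tri_area), volume = abs(sum(tri_vol)))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

face_normal <- function(f, pts) {
  cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
}

# Flip vertex order so the face normal points away from the interior point.
orient_face <- function(f, pts, interior) {
  nrm <- face_normal(f, pts)
  if (sum(nrm * (interior - pts[f[1], ])) > 0) f[c(1, 3, 2)] else f
}

#' Convex-hull surface area of a point cloud
#'
#' For voxel-grid bodies the candidate set is first reduced to per-column
#' extreme points (for each (y, z) column the min- and max-x points), which
#' leaves the hull unchanged while keeping the incremental construction
#' fast.
#'
#' @param pts numeric matrix (n x 3) of points (nm).
#' @return hull surface area (nm^2).
#' @export
convex_hull_area <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) >= 4L) pts <- hull_candidates(pts)
  convex_hull_3d(pts)$area
}

# Keep, for every (y, z) pair, only the min-x and max-x points: interior
# points of a column are convex combinations of its extremes, so the hull is
# unchanged.
hull_candidates <- function(pts) {
  key <- paste(pts[, 2], pts[, 3])
  idx <- unlist(lapply(split(seq_len(nrow(pts)), key), function(ii) {
    ii[c(which.min(pts[ii, 1]), which.max(pts[ii, 1]))]
  }), use.names = FALSE)
  pts[unique(idx), , drop = FALSE]
}
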