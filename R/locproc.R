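#' Geometric-mean quality rank of a localization event
#'
#' Combines three self-normalized quality metrics (each in `[0, 1]`) into a
#' single rank by multiplying them and taking the cube root. Events with a
#' rank below 0.8 are rejected by the downstream filter.
#'
#' The rank is symmetric in its arguments and monotone non-decreasing in
#' each; a zero in any metric annihilates it.
#'
#' @param m1,m2,m3 numeric vectors of normalized metrics in `[0, 1]`.
#' @return the geometric mean `(m1*m2*m3)^(1/3)`.
#' @export
score_quality <- function(m1, m2, m3) {
  m <- cbind(m1, m2, m3)
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    stop_ct("quality metrics must lie in [0, 1]")
  (m1 * m2 * m3)^(1 / 3)
}

#' Rank-based self-normalization of the three raw quality metrics
#'
#' The three raw metrics are (1) the PSF-to-cutout photon ratio, (2) the
#' total cutout photons and (3) the axial offset between the fitted position
#' and the objective piezo (smaller magnitude is better, so its negated
#' absolute value is ranked). Each metric is min–max scaled on its ranks so
#' the worst event maps to 0 and the best to 1 within the acquisition.
#'
#' @param locs a localization table.
#' @return a 3-column matrix of normalized metrics (`m1`, `m2`, `m3`).
#' @export
normalize_metrics <- function(locs) {
  rank01 <- function(v) {
    if (length(v) == 1L) return(1)
    r <- rank(v, ties.method = "average")
    (r - min(r)) / max(max(r) - min(r), .Machine$double.eps)
  }
  cbind(m1 = rank01(locs$psf_photons / pmax(locs$cutout_photons,
                                            .Machine$double.eps)),
        m2 = rank01(locs$cutout_photons),
        m3 = rank01(-abs(locs$z_offset_nm)))
}

#' Quality filter on localization events
#'
#' Ranks each event by [score_quality()] over the self-normalized metrics
#' and keeps events with rank at or above `threshold` (default 0.8).
#'
#' @param locs a localization table.
#' @param threshold minimal accepted quality rank.
#' @return the filtered localization table; the computed ranks are attached
#'   as attribute `"quality_rank"`.
#' @export
filter_quality <- function(locs, threshold = 0.8) {
  if (!nrow(locs)) return(locs)
  m <- normalize_metrics(locs)
  q <- score_quality(m[, 1], m[, 2], m[, 3])
  out <- locs[q >= threshold, , drop = FALSE]
  attr(out, "quality_rank") <- q[q >= threshold]
  out
}

#' Axial-precision filter
#'
#' Removes localizations whose axial precision is worse than `max_nm`
#' (strictly greater; events at exactly `max_nm` are kept).
#'
#' @param locs a localization table.
#' @param max_nm axial precision cutoff in nm (default 100).
#' @return the filtered table.
#' @export
filter_axial <- function(locs, max_nm = 100) {
  locs[locs$ax_prec_nm <= max_nm, , drop = FALSE]
}

#' Merge repeated detections of a single emitter
#'
#' Candidate events whose lateral position stays within 2 pixels of the
#' run's first event across up to 7 consecutive frames (no frame gap larger
#' than 1) are collapsed into one event. The merged position is the
#' precision-weighted mean (lateral precision weights x/y, axial weights z),
#' photon counts are summed, the merged precision is the inverse-variance
#' combination, and the merged frame is the run's first frame. Runs never
#' span hybridization rounds.
#'
#' @param locs a localization table sorted by frame.
#' @param pixel_size camera pixel size in nm (default 100).
#' @param max_pixels maximal lateral excursion in pixels (default 2).
#' @param max_span maximal number of frames in a run (default 7).
#' @return the merged localization table (never more rows than the input;
#'   idempotent).
#' @export
merge_repeats <- function(locs, pixel_size = 100, max_pixels = 2,
                          max_span = 7) {
  if (!nrow(locs)) return(locs)
  if (is.unsorted(locs$frame)) stop_ct("events must be sorted by frame")
  if (pixel_size <= 0) stop_ct("pixel_size must be > 0")
  max_d <- max_pixels * pixel_size

  n <- nrow(locs)
  run_id <- integer(n)
  cur <- 1L
  run_id[1] <- 1L
  start_i <- 1L
  for (i in seq_len(n)[-1]) {
    same_round <- locs$round[i] == locs$round[start_i]
    gap_ok <- locs$frame[i] - locs$frame[i - 1L] <= 1L
    span_ok <- locs$frame[i] - locs$frame[start_i] <= max_span - 1L
    dxy <- sqrt((locs$x_nm[i] - locs$x_nm[start_i])^2 +
                (locs$y_nm[i] - locs$y_nm[start_i])^2)
    if (same_round && gap_ok && span_ok && dxy <= max_d) {
      run_id[i] <- cur
    } else {
      cur <- cur + 1L
      run_id[i] <- cur
      start_i <- i
    }
  }

  merge_run <- function(idx) {
    if (length(idx) == 1L) return(locs[idx, , drop = FALSE])
    sub <- locs[idx, , drop = FALSE]
    wl <- 1 / sub$lat_prec_nm^2
    wa <- 1 / sub$ax_prec_nm^2
    out <- sub[1, , drop = FALSE]
    out$x_nm <- sum(sub$x_nm * wl) / sum(wl)
    out$y_nm <- sum(sub$y_nm * wl) / sum(wl)
    out$z_nm <- sum(sub$z_nm * wa) / sum(wa)
    out$psf_photons <- sum(sub$psf_photons)
    out$cutout_photons <- sum(sub$cutout_photons)
    out$z_offset_nm <- sum(sub$z_offset_nm * wa) / sum(wa)
    out$lat_prec_nm <- sqrt(1 / sum(wl))
    out$ax_prec_nm <- sqrt(1 / sum(wa))
    out
  }
  merged <- do.call(rbind, lapply(split(seq_len(n), run_id), merge_run))
  rownames(merged) <- NULL
  class(merged) <- class(locs)
  merged
}

#' Fiducial-based drift correction
#'
#' Estimates stage drift as the displacement of the fiducial-marker centre
#' of mass in non-overlapping frame windows relative to the first window,
#' linearly interpolated between window centres, and subtracts it from every
#' localization. Windows without fiducial coverage are interpolated from
#' their neighbours and flagged.
#'
#' @param locs a localization table.
#' @param fiducials a fiducial table (`marker_id, frame, x_nm, y_nm, z_nm`).
#' @param window window width in frames (default 1000).
#' @return a list with `locs` (corrected table), `drift` (per-window trace:
#'   `window, frame_center, dx, dy, dz, interpolated`), and `drift_at`
#'   (function frame -> drift vector, for audit / re-injection).
#' @export
drift_correct <- function(locs, fiducials, window = 1000) {
  if (is.null(fiducials) || !nrow(fiducials))
    stop_ct("drift correction requires at least one fiducial marker")
  if (window < 1) stop_ct("window must be >= 1")

  fmax <- max(locs$frame, fiducials$frame)
  breaks <- seq(0L, fmax + window, by = window)
  nw <- length(breaks) - 1L
  win_of <- function(fr) pmin(pmax(findInterval(fr, breaks,
                                                rightmost.closed = TRUE), 1L), nw)
  fw <- win_of(fiducials$frame)
  com <- matrix(NA_real_, nw, 3)
  for (w in unique(fw)) {
    sel <- fw == w
    com[w, ] <- c(mean(fiducials$x_nm[sel]), mean(fiducials$y_nm[sel]),
                  mean(fiducials$z_nm[sel]))
  }
  covered <- which(!is.na(com[, 1]))
  interpolated <- is.na(com[, 1])
  if (any(interpolated)) {
    for (c in 1:3)
      com[, c] <- stats::approx(covered, com[covered, c], xout = seq_len(nw),
                                rule = 2)$y
  }
  drift <- sweep(com, 2, com[covered[1], ])
  centers <- (breaks[-length(breaks)] + breaks[-1] - 1) / 2

  drift_at <- function(frame) {
    vapply(1:3, function(c)
      stats::approx(centers, drift[, c], xout = frame, rule = 2)$y,
      numeric(length(frame)))
  }
  d <- drift_at(locs$frame)
  if (nrow(locs) == 1L) d <- matrix(d, nrow = 1)
  out <- locs
  out$x_nm <- locs$x_nm - d[, 1]
  out$y_nm <- locs$y_nm - d[, 2]
  out$z_nm <- locs$z_nm - d[, 3]
  trace <- data.frame(window = seq_len(nw), frame_center = centers,
                      dx = drift[, 1], dy = drift[, 2], dz = drift[, 3],
                      interpolated = interpolated)
  list(locs = out, drift = trace, drift_at = drift_at)
}

#' DBSCAN clustering of localizations
#'
#' Density-based clustering with `eps = max_distance` and
#' `minPts = min_points` (the neighbourhood count includes the point
#' itself). Core points are connected into clusters; border points are
#' assigned to the cluster of their nearest core neighbour (lowest index on
#' ties), making the labelling deterministic and order-independent.
#' Remaining points are noise (label 0). Clusters are relabelled 1, 2, ...
#' by decreasing size (ties by smallest member index).
#'
#' @param locs a localization table (or a matrix/data frame with columns
#'   `x_nm, y_nm, z_nm`).
#' @param max_distance DBSCAN eps in nm (default 150).
#' @param min_points DBSCAN minPts (default 10).
#' @return a list with `labels` (integer vector, 0 = noise) and `clusters`
#'   (list of row-index vectors, sorted by decreasing size).
#' @export
extract_clusters <- function(locs, max_distance = 150, min_points = 10) {
  if (max_distance <= 0) stop_ct("max_distance must be > 0")
  if (min_points < 1) stop_ct("min_points must be >= 1")
  pts <- as.matrix(as.data.frame(locs)[, c("x_nm", "y_nm", "z_nm")])
  n <- nrow(pts)
  if (!n) return(list(labels = integer(0), clusters = list()))
  nb <- cpp_radius_neighbors(pts, max_distance)
  dbscan_from_neighbors(pts, nb, min_points)
}

# Deterministic DBSCAN given neighbour lists (1-based, self-inclusive).
dbscan_from_neighbors <- function(pts, nb, min_points) {
  n <- nrow(pts)
  is_core <- vapply(nb, length, integer(1)) >= min_points
  labels <- integer(n)
  cl <- 0L
  # connected components over core points
  for (i in seq_len(n)) {
    if (!is_core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      cores <- nb[[j]][is_core[nb[[j]]]]
      new <- cores[labels[cores] == 0L]
      labels[new] <- cl
      queue <- c(queue, new)
    }
  }
  # border points: nearest core neighbour, lowest index on ties
  for (i in seq_len(n)) {
    if (is_core[i] || labels[i] != 0L) next
    cores <- nb[[i]][is_core[nb[[i]]]]
    if (!length(cores)) next
    d <- sqrt(colSums((t(pts[cores, , drop = FALSE]) - pts[i, ])^2))
    labels[i] <- labels[cores[which.min(d)]]
  }
  # relabel by decreasing size, ties by smallest member index
  if (cl > 0L) {
    sizes <- tabulate(labels, nbins = cl)
    first <- vapply(seq_len(cl), function(k) min(which(labels == k)),
                    integer(1))
    ord <- order(-sizes, first)
    relab <- integer(cl)
    relab[ord] <- seq_len(cl)
    labels[labels > 0L] <- relab[labels[labels > 0L]]
  }
  clusters <- lapply(seq_len(cl), function(k) which(labels == k))
  list(labels = labels, clusters = clusters)
}

#' Standard localization processing chain
#'
#' Applies, in order: quality filter, repeat merging, axial-precision
#' filter, drift correction (when fiducials are given), and DBSCAN cluster
#' extraction per hybridization round.
#'
#' @param locs a localization table.
#' @param fiducials optional fiducial table for drift correction.
#' @param quality_threshold minimal quality rank (default 0.8).
#' @param max_axial_precision axial cutoff in nm (default 100).
#' @param eps,min_points DBSCAN parameters (defaults 150 nm, 10).
#' @param pixel_size camera pixel size for repeat merging (nm).
#' @param drift_window drift-correction window in frames.
#' @return a list with the processed `locs`, the `drift` trace (or NULL) and
#'   `clusters_by_round` (per round: the [extract_clusters()] result).
#' @export
process_localizations <- function(locs, fiducials = NULL,
                                  quality_threshold = 0.8,
                                  max_axial_precision = 100, eps = 150,
                                  min_points = 10, pixel_size = 100,
                                  drift_window = 1000) {
  out <- filter_quality(locs, quality_threshold)
  out <- out[order(out$frame), , drop = FALSE]
  out <- merge_repeats(out, pixel_size = pixel_size)
  out <- filter_axial(out, max_axial_precision)
  drift <- NULL
  if (!is.null(fiducials) && nrow(fiducials)) {
    dc <- drift_correct(out, fiducials, window = drift_window)
    out <- dc$locs
    drift <- dc$drift
  }
  rounds <- sort(unique(out$round))
  clusters_by_round <- lapply(rounds, function(r)
    extract_clusters(out[out$round == r, , drop = FALSE], eps, min_points))
  names(clusters_by_round) <- as.character(rounds)
  list(locs = out, drift = drift, clusters_by_round = clusters_by_round)
}
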