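# Synthetic ground truth: chromatin chains, localization tables and contact
# matrices with the statistical structure the pipeline assumes.

#' Default walk segments
#'
#' Nine contiguous segments tiling chr19:7,400,000-15,560,000 (8.16 Mb),
#' with sizes from 360 kb to 1.8 Mb (0-based half-open BED coordinates).
#'
#' @return a BED-style data frame (`chrom, start, end, name`).
#' @export
walk_segments <- function() {
  sizes <- c(1800000, 360000, 960000, 680000, 720000, 1080000, 840000,
             1120000, 600000)
  ends <- 7400000 + cumsum(sizes)
  data.frame(chrom = "chr19", start = c(7400000, head(ends, -1)),
             end = ends, name = paste0("CS", 1:9))
}

#' Self-avoiding confined random chain
#'
#' Grows a bead chain with fixed bond length inside a confinement sphere,
#' rejecting steps closer than `min_dist` to any non-bonded bead
#' (backtracking on dead ends). Optional per-bead target spheres
#' (`centers`, `radii`) plant a spatial layout, e.g. the two-block
#' arrangement with a compact centre and proximal ends.
#'
#' @param n_beads chain length (>= 2).
#' @param bond_length fixed bond length (nm).
#' @param confinement_radius radius of the global confinement sphere (nm).
#' @param seed RNG seed.
#' @param min_dist self-avoidance distance (nm; default `bond_length / 2`).
#' @param centers optional n x 3 matrix of per-bead target centres (nm).
#' @param radii optional per-bead target radii (nm).
#' @param r bead radius stored on the model (nm).
#' @param bin_size genomic bin per bead (bp).
#' @return a `bead_model`.
#' @export
make_chain <- function(n_beads, bond_length, confinement_radius,
                       seed = NULL, min_dist = bond_length / 2,
                       centers = NULL, radii = NULL, r = 15,
                       bin_size = 10000) {
  if (n_beads < 2) stop_ct("n_beads must be >= 2")
  if (bond_length <= 0 || confinement_radius <= 0)
    stop_ct("lengths must be > 0")
  # feasibility: packing fraction of the self-avoidance spheres
  pack <- n_beads * (min_dist / 2)^3 / confinement_radius^3
  if (pack > 0.3)
    stop_ct(sprintf("infeasible packing (density %.2f > 0.3)", pack))

  with_seed(seed, {
    X <- matrix(NA_real_, n_beads, 3)
    X[1, ] <- if (is.null(centers)) c(0, 0, 0) else centers[1, ]
    i <- 2L
    backtracks <- 0L
    while (i <= n_beads) {
      placed <- FALSE
      for (try in 1:200) {
        dir <- rnorm(3)
        if (!is.null(centers)) {
          # bias toward the bead's target centre, harder on later retries
          pull <- centers[i, ] - X[i - 1, ]
          pn <- sqrt(sum(pull^2))
          if (pn > 1e-9)
            dir <- dir / sqrt(sum(dir^2)) +
              (0.6 + try / 50) * (pn / radii[i]) * pull / pn
        }
        cand <- X[i - 1, ] + bond_length * dir / sqrt(sum(dir^2))
        if (sum(cand^2) > confinement_radius^2) next
        if (!is.null(centers) &&
            sum((cand - centers[i, ])^2) > radii[i]^2) next
        if (i > 2L) {
          prev <- X[seq_len(i - 2L), , drop = FALSE]
          if (min(colSums((t(prev) - cand)^2)) < min_dist^2) next
        }
        X[i, ] <- cand
        placed <- TRUE
        break
      }
      if (placed) {
        i <- i + 1L
      } else {
        backtracks <- backtracks + 1L
        if (backtracks > 50 * n_beads)
          stop_ct("infeasible packing: chain growth failed")
        i <- max(2L, i - 5L)
      }
    }
    bead_model(X, r = r, bin_size = bin_size)
  })
}

# Per-bead target centres/radii for the planted two-block layout: central
# segments (default CS3-7) in a compact core, peripheral segments on a
# shell with the first and last segment adjacent. Per-bead targets are
# linearly interpolated between segment-midpoint knots so the target tube
# is continuous and chain growth across segment boundaries stays feasible.
two_block_layout <- function(beads_per_segment, core_radius = 80,
                             shell_radius = 500, core_extent = 110,
                             peri_extent = 160,
                             central = 3:7) {
  k <- length(beads_per_segment)
  if (k != 9L) stop_ct("two-block layout expects 9 segments")
  centers <- matrix(0, k, 3)
  radii <- rep(peri_extent, k)
  # peripheral ring: CS1 and CS9 share a shell neighbourhood (proximal
  # ends); CS2 / CS8 sit between the ends and the core so consecutive
  # segment centres stay within reach of the chain contour
  centers[1, ] <- c(shell_radius + 50, 100, 0)
  centers[9, ] <- c(shell_radius + 50, -100, 0)
  centers[2, ] <- c(shell_radius - 40, 140, 60)
  centers[8, ] <- c(shell_radius - 40, -140, -60)
  # central: small ring around the origin, rotated so no central segment
  # points toward the peripheral shell (+x)
  ang <- pi / 2 +
    seq(0, 2 * pi, length.out = length(central) + 1)[seq_along(central)]
  for (t in seq_along(central)) {
    centers[central[t], ] <- core_radius *
      c(cos(ang[t]), sin(ang[t]), 0.5 * sin(2 * ang[t]))
    radii[central[t]] <- core_extent
  }
  # interpolate bead targets through segment-midpoint knots
  n <- sum(beads_per_segment)
  ends <- cumsum(beads_per_segment)
  knots <- ends - beads_per_segment / 2
  bead_centers <- vapply(1:3, function(c)
    stats::approx(knots, centers[, c], xout = seq_len(n), rule = 2)$y,
    numeric(n))
  bead_radii <- pmax(stats::approx(knots, radii, xout = seq_len(n),
                                   rule = 2)$y, core_extent)
  list(centers = bead_centers, radii = bead_radii)
}

#' Synthetic diploid nucleus with a planted two-block walk
#'
#' Builds two homologous ground-truth chains over the default 9-segment
#' walk: segments CS3-CS7 compact and central, CS1/CS2/CS8/CS9 peripheral
#' with the two walk ends spatially proximal. Homolog 2 is displaced so the
#' homologs are resolvable.
#'
#' @param seed RNG seed (drives both chains).
#' @param bin_size genomic bin per bead (bp; default 40000 keeps the walk
#'   at 204 beads per homolog).
#' @param bond_length bond length (nm).
#' @param homolog_offset displacement of homolog 2 (nm).
#' @param segments segment table (default [walk_segments()]).
#' @return a list of class `synthetic_nucleus`: `homologs` (two
#'   `bead_model`s), `segments`, `segment_of_bead`, `seed`.
#' @export
synthetic_nucleus <- function(seed = 1, bin_size = 40000, bond_length = 40,
                              homolog_offset = c(3000, 0, 0),
                              segments = walk_segments()) {
  beads_per_segment <- (segments$end - segments$start) / bin_size
  if (any(beads_per_segment != round(beads_per_segment)))
    stop_ct("segment sizes must be multiples of bin_size")
  beads_per_segment <- as.integer(beads_per_segment)
  layout <- two_block_layout(beads_per_segment)
  n <- sum(beads_per_segment)
  homologs <- lapply(1:2, function(h) {
    chain <- make_chain(n, bond_length, confinement_radius = 1200,
                        seed = seed * 1000L + h, min_dist = bond_length / 2,
                        centers = layout$centers, radii = layout$radii,
                        bin_size = bin_size)
    if (h == 2)
      chain$coords <- sweep(chain$coords, 2, homolog_offset, "+")
    chain$start <- segments$start[1]
    chain
  })
  structure(list(homologs = homologs, segments = segments,
                 segment_of_bead = rep(seq_len(nrow(segments)),
                                       beads_per_segment),
                 seed = seed),
            class = "synthetic_nucleus")
}

#' Simulate localization data from a bead model
#'
#' Per bead, a Poisson number of localization events displaced by axis-wise
#' Gaussian noise (lateral / axial precision); uniform background events at
#' `background_fraction` of the signal count; linear drift applied to all
#' events and to three synthetic fiducial markers. Per-event precisions and
#' the three quality metrics are emitted so the localization filters are
#' exercised: a latent quality variable drives the PSF photon count, the
#' PSF-to-cutout ratio and the axial offset, and a small fraction of events
#' carries axial precision worse than 100 nm.
#'
#' @param model a `bead_model` (one homolog).
#' @param segment_of_bead integer segment index per bead (drives the
#'   hybridization `round` column; default all 1).
#' @param events_per_bead mean events per bead (default 30).
#' @param lat_sigma,ax_sigma localization noise (nm; defaults 11 / 47).
#' @param background_fraction background events as a fraction of signal
#'   (default 0.05).
#' @param drift total linear drift over the recording (length-3, nm).
#' @param n_frames recording length in frames (default 10000).
#' @param bad_axial_fraction fraction of events with axial precision worse
#'   than 100 nm (default 0.05).
#' @param repeat_prob probability that an event re-fires in the next frame
#'   (exercises repeat merging; default 0.15).
#' @param seed RNG seed.
#' @return a list with `locs` (localization table) and `fiducials`.
#' @export
simulate_localizations <- function(model, segment_of_bead = NULL,
                                   events_per_bead = 30, lat_sigma = 11,
                                   ax_sigma = 47,
                                   background_fraction = 0.05,
                                   drift = c(0, 0, 0), n_frames = 10000,
                                   bad_axial_fraction = 0.05,
                                   repeat_prob = 0.15, seed = NULL) {
  stopifnot(events_per_bead >= 0, background_fraction >= 0)
  X <- model$coords
  nb <- nrow(X)
  segment_of_bead <- segment_of_bead %||% rep(1L, nb)
  with_seed(seed, {
    k <- rpois(nb, events_per_bead)
    bead_idx <- rep(seq_len(nb), k)
    ns <- length(bead_idx)
    nbg <- rpois(1, background_fraction * max(ns, 1))
    lo <- apply(X, 2, min) - 300
    hi <- apply(X, 2, max) + 300

    pos <- rbind(
      X[bead_idx, , drop = FALSE] +
        cbind(rnorm(ns, 0, lat_sigma), rnorm(ns, 0, lat_sigma),
              rnorm(ns, 0, ax_sigma)),
      cbind(runif(nbg, lo[1], hi[1]), runif(nbg, lo[2], hi[2]),
            runif(nbg, lo[3], hi[3])))
    round_id <- c(segment_of_bead[bead_idx],
                  sample(unique(segment_of_bead), nbg, replace = TRUE))
    n <- ns + nbg
    if (!n)
      return(list(
        locs = validate_localizations(
          data.frame(x_nm = numeric(0), y_nm = numeric(0),
                     z_nm = numeric(0), frame = integer(0),
                     psf_photons = numeric(0), cutout_photons = numeric(0),
                     z_offset_nm = numeric(0), lat_prec_nm = numeric(0),
                     ax_prec_nm = numeric(0), round = integer(0))),
        fiducials = data.frame()))

    # latent quality drives the three raw metrics; background is worse
    q <- c(runif(ns), runif(nbg) * 0.8)
    psf <- pmax(500 + 4000 * q + rnorm(n, 0, 100), 10)
    ratio <- pmin(pmax(0.4 + 0.55 * q + rnorm(n, 0, 0.02), 0.05), 0.999)
    frame <- sample.int(n_frames, n, replace = TRUE) - 1L
    lat_prec <- pmax(rnorm(n, 11, 1.5), 3)
    ax_prec <- pmax(rnorm(n, 47, 6), 10)
    bad <- runif(n) < bad_axial_fraction
    ax_prec[bad] <- runif(sum(bad), 101, 180)

    locs <- data.frame(
      x_nm = pos[, 1], y_nm = pos[, 2], z_nm = pos[, 3], frame = frame,
      psf_photons = psf, cutout_photons = psf / ratio,
      z_offset_nm = rnorm(n, 0, 20 + 150 * (1 - q)),
      lat_prec_nm = lat_prec, ax_prec_nm = ax_prec,
      round = as.integer(round_id))

    # re-fired emitters in the following frame (merged by merge_repeats)
    rep_sel <- which(runif(n) < repeat_prob & frame < n_frames - 1L)
    if (length(rep_sel)) {
      reps <- locs[rep_sel, , drop = FALSE]
      reps$frame <- reps$frame + 1L
      reps$x_nm <- reps$x_nm + rnorm(nrow(reps), 0, 3)
      reps$y_nm <- reps$y_nm + rnorm(nrow(reps), 0, 3)
      locs <- rbind(locs, reps)
    }

    # linear drift over the recording
    f <- locs$frame / max(n_frames - 1L, 1L)
    locs$x_nm <- locs$x_nm + drift[1] * f
    locs$y_nm <- locs$y_nm + drift[2] * f
    locs$z_nm <- locs$z_nm + drift[3] * f
    locs <- locs[order(locs$frame), , drop = FALSE]
    rownames(locs) <- NULL

    fid_base <- rbind(lo, hi, c(lo[1], hi[2], lo[3]))
    fid_frames <- seq(0L, n_frames - 1L, by = 10L)
    fid <- do.call(rbind, lapply(1:3, function(m) {
      ff <- fid_frames / max(n_frames - 1L, 1L)
      data.frame(marker_id = m, frame = fid_frames,
                 x_nm = fid_base[m, 1] + drift[1] * ff + rnorm(length(ff), 0, 1),
                 y_nm = fid_base[m, 2] + drift[2] * ff + rnorm(length(ff), 0, 1),
                 z_nm = fid_base[m, 3] + drift[3] * ff + rnorm(length(ff), 0, 1))
    }))
    list(locs = validate_localizations(locs), fiducials = fid)
  })
}

#' Simulate a full diploid nucleus recording
#'
#' Combines [synthetic_nucleus()] and [simulate_localizations()] for both
#' homologs into one localization table (shared frames, drift and
#' fiducials).
#'
#' @param seed RNG seed.
#' @param drift total linear drift (nm).
#' @param ... passed to [simulate_localizations()].
#' @param nucleus an existing `synthetic_nucleus` (built from `seed` when
#'   NULL).
#' @return a list with `nucleus`, `locs`, `fiducials`.
#' @export
simulate_nucleus <- function(seed = 1, drift = c(30, -20, 10),
                             nucleus = NULL, ...) {
  nucleus <- nucleus %||% synthetic_nucleus(seed)
  sims <- lapply(1:2, function(h)
    simulate_localizations(nucleus$homologs[[h]], nucleus$segment_of_bead,
                           drift = drift, seed = seed * 100L + h, ...))
  locs <- rbind(sims[[1]]$locs, sims[[2]]$locs)
  locs <- locs[order(locs$frame), , drop = FALSE]
  rownames(locs) <- NULL
  class(locs) <- class(sims[[1]]$locs)
  list(nucleus = nucleus, locs = locs, fiducials = sims[[1]]$fiducials)
}
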