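# End-to-end analysis of one nucleus and the configurable pipeline runner.

#' Analyse one diploid nucleus recording
#'
#' Runs the localization-processing chain ([process_localizations()]),
#' assigns the two largest DBSCAN clusters of each hybridization round to
#' the two homologs by nearest running centre of mass, builds per-segment
#' density maps on a common per-homolog grid, and assembles the structural
#' feature table.
#'
#' @param locs localization table of the whole recording.
#' @param fiducials fiducial table (or NULL to skip drift correction).
#' @param segments segment BED table; row order maps hybridization round r
#'   to segment r.
#' @param nucleus_id identifier carried into the feature table.
#' @param voxel_size density-map voxel (nm).
#' @param sigma kernel width (`"auto"` = mean precision per cluster).
#' @param quality_threshold,max_axial_precision,eps,min_points,drift_window
#'   localization-processing parameters (defaults are the standard chain).
#' @return a list with `homologs` (per homolog: `maps`, `clusters`),
#'   `features` (raw feature table), `locproc` (processed localizations).
#' @export
analyze_nucleus <- function(locs, fiducials, segments, nucleus_id = "N1",
                            voxel_size = 25, sigma = "auto",
                            quality_threshold = 0.8,
                            max_axial_precision = 100, eps = 150,
                            min_points = 10, drift_window = 1000) {
  proc <- process_localizations(locs, fiducials,
                                quality_threshold = quality_threshold,
                                max_axial_precision = max_axial_precision,
                                eps = eps, min_points = min_points,
                                drift_window = drift_window)
  k <- nrow(segments)
  clusters <- assign_homologs(proc, k)

  homologs <- lapply(1:2, function(h) {
    segs <- clusters[[h]]
    pts <- do.call(rbind, segs)
    grid <- common_grid(pts, voxel_size, pad = 150)
    maps <- lapply(segs, function(cl)
      build_density_map(cl, voxel_size = voxel_size, sigma = sigma,
                        grid = grid))
    names(maps) <- segments$name
    list(maps = maps, clusters = segs)
  })
  feats <- feature_table(lapply(1:2, function(h)
    list(maps = homologs[[h]]$maps, nucleus = nucleus_id, homolog = h)))
  list(homologs = homologs, features = feats, locproc = proc)
}

# Per round, take the two largest clusters and assign them to homologs by
# nearest running homolog centre of mass (round 1 seeds the two homologs,
# ordered by x so the labelling is deterministic).
assign_homologs <- function(proc, n_rounds) {
  out <- list(vector("list", n_rounds), vector("list", n_rounds))
  ref <- NULL
  for (r in seq_len(n_rounds)) {
    cl <- proc$clusters_by_round[[as.character(r)]]
    if (is.null(cl) || length(cl$clusters) < 2L)
      stop_ct("round ", r, ": fewer than 2 clusters found")
    sub <- proc$locs[proc$locs$round == r, , drop = FALSE]
    two <- lapply(cl$clusters[1:2], function(ii) sub[ii, , drop = FALSE])
    coms <- t(vapply(two, function(d)
      colMeans(as.matrix(d[, c("x_nm", "y_nm", "z_nm")])), numeric(3)))
    if (is.null(ref)) {
      ord <- order(coms[, 1])
      ref <- coms[ord, , drop = FALSE]
      two <- two[ord]
    } else {
      d11 <- sum((coms[1, ] - ref[1, ])^2) + sum((coms[2, ] - ref[2, ])^2)
      d12 <- sum((coms[1, ] - ref[2, ])^2) + sum((coms[2, ] - ref[1, ])^2)
      if (d12 < d11) {
        two <- two[c(2, 1)]
        coms <- coms[c(2, 1), , drop = FALSE]
      }
      ref <- (ref * (r - 1) + coms) / r  # running mean
    }
    out[[1]][[r]] <- two[[1]]
    out[[2]][[r]] <- two[[2]]
  }
  out
}

# Empty density-map frame covering `pts` with padding (nm).
common_grid <- function(pts, voxel_size, pad = 150) {
  P <- as.matrix(as.data.frame(pts)[, c("x_nm", "y_nm", "z_nm")])
  lo <- apply(P, 2, min) - pad
  hi <- apply(P, 2, max) + pad
  d <- pmax(floor((hi - lo) / voxel_size + 0.5) + 1L, 1L)
  density_map(array(0, dim = d), lo, voxel_size)
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order (`simulate` ->
#' `locproc` -> `densmap` -> `metrics`; `imgr` independently), writes every
#' output file into `out_dir` and records them, with content hashes, in a
#' JSON run manifest. Identical configuration and seed give identical
#' hashes.
#'
#' Recognised config keys: `stages` (character vector), `seed`,
#' `n_nuclei`, `params` (named overrides: `voxel_size, sigma, eps,
#' min_points, quality_threshold, max_axial_precision, drift_window,
#' events_per_bead, n_placements, percentile`), `out_dir`.
#'
#' @param config a named list, or path to a JSON file.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return the manifest (invisibly), also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  known <- c("stages", "seed", "n_nuclei", "params", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop_ct("unknown config keys: ", paste(unknown, collapse = ", "))
  out_dir <- out_dir %||% config$out_dir %||% stop_ct("out_dir required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% character(0)
  seed <- config$seed %||% 1L
  n_nuclei <- config$n_nuclei %||% 1L
  p <- config$params %||% list()
  outputs <- character(0)

  segments <- walk_segments()
  if ("simulate" %in% stages || any(c("locproc", "densmap", "metrics")
                                    %in% stages)) {
    sims <- lapply(seq_len(n_nuclei), function(i)
      simulate_nucleus(seed = seed + i - 1L,
                       events_per_bead = p$events_per_bead %||% 30))
  }
  if ("simulate" %in% stages) {
    for (i in seq_len(n_nuclei)) {
      pre <- file.path(out_dir, sprintf("nucleus%02d", i))
      outputs <- c(outputs,
                   write_localizations(sims[[i]]$locs,
                                       paste0(pre, "_localizations.csv")),
                   write_fiducials(sims[[i]]$fiducials,
                                   paste0(pre, "_fiducials.csv")))
      for (h in 1:2)
        outputs <- c(outputs, write_xyz_model(
          sims[[i]]$nucleus$homologs[[h]],
          paste0(pre, sprintf("_truth_h%d.xyz", h))))
    }
    outputs <- c(outputs, write_bed(segments,
                                    file.path(out_dir, "segments.bed")))
  }

  if (any(c("locproc", "densmap", "metrics") %in% stages)) {
    analyses <- lapply(seq_len(n_nuclei), function(i)
      analyze_nucleus(sims[[i]]$locs, sims[[i]]$fiducials, segments,
                      nucleus_id = sprintf("N%02d", i),
                      voxel_size = p$voxel_size %||% 25,
                      eps = p$eps %||% 150,
                      min_points = p$min_points %||% 10,
                      quality_threshold = p$quality_threshold %||% 0.8,
                      max_axial_precision = p$max_axial_precision %||% 100,
                      drift_window = p$drift_window %||% 1000))
    if ("densmap" %in% stages) {
      for (i in seq_len(n_nuclei)) for (h in 1:2) {
        maps <- analyses[[i]]$homologs[[h]]$maps
        for (s in names(maps)) {
          f <- file.path(out_dir, sprintf("nucleus%02d_h%d_%s.mrc", i, h, s))
          outputs <- c(outputs, write_mrc(maps[[s]], f))
        }
      }
    }
    if ("metrics" %in% stages) {
      feats <- do.call(rbind, lapply(analyses, function(a) a$features))
      feats <- zscore_features(feats, segments)
      f <- file.path(out_dir, "features.tsv")
      write.table(feats, f, sep = "\t", row.names = FALSE, quote = FALSE)
      outputs <- c(outputs, f)
    }
  }

  if ("imgr" %in% stages) {
    # fit the first nucleus' homolog-1 truth chain back into its own map
    nuc <- synthetic_nucleus(seed)
    truth <- nuc$homologs[[1]]
    ens <- lapply(1:5, function(i) {
      m <- truth
      m$coords <- m$coords + matrix(rnorm(length(m$coords), 0, 20),
                                    ncol = 3)
      m
    })
    contacts <- contacts_from_ensemble(ens, cutoff = 4 * truth$r)
    rs <- restraints_from_contacts(contacts, bin_size = truth$bin_size,
                                   bead_radius = truth$r)
    f <- file.path(out_dir, "restraints.tsv")
    outputs <- c(outputs, write_restraints(rs, f))
  }

  manifest <- list(
    config = config,
    outputs = lapply(sort(outputs), function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
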