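#' Localization tables
#'
#' A localization table holds one row per single-molecule detection event:
#' coordinates in nm, the acquisition frame, photon counts for the fitted
#' point-spread function and the camera cutout, the axial offset between the
#' fitted position and the objective piezo, the estimated lateral and axial
#' localization precisions (Cramér–Rao derived, in nm), and the
#' hybridization round that produced the event.
#'
#' @param x_nm,y_nm,z_nm numeric coordinates (nm).
#' @param frame integer acquisition frame index (>= 0).
#' @param psf_photons,cutout_photons photons attributed to the PSF fit and to
#'   the full camera cutout; `cutout_photons >= psf_photons >= 0`.
#' @param z_offset_nm axial mismatch between fit and piezo position (nm).
#' @param lat_prec_nm,ax_prec_nm estimated precisions (nm, > 0).
#' @param round integer hybridization round (>= 1).
#' @return A `data.frame` of class `localizations`.
#' @export
localizations <- function(x_nm, y_nm, z_nm, frame, psf_photons,
                          cutout_photons, z_offset_nm, lat_prec_nm,
                          ax_prec_nm, round = 1L) {
  df <- data.frame(x_nm = as.numeric(x_nm), y_nm = as.numeric(y_nm),
                   z_nm = as.numeric(z_nm), frame = as.integer(frame),
                   psf_photons = as.numeric(psf_photons),
                   cutout_photons = as.numeric(cutout_photons),
                   z_offset_nm = as.numeric(z_offset_nm),
                   lat_prec_nm = as.numeric(lat_prec_nm),
                   ax_prec_nm = as.numeric(ax_prec_nm),
                   round = as.integer(round))
  validate_localizations(df)
}

loc_columns <- c("x_nm", "y_nm", "z_nm", "frame", "psf_photons",
                 "cutout_photons", "z_offset_nm", "lat_prec_nm",
                 "ax_prec_nm", "round")

#' Validate a localization table
#'
#' Checks the column contract and the event invariants: finite coordinates,
#' `cutout_photons >= psf_photons >= 0`, positive precisions.
#'
#' @param df a data frame with the columns of [localizations()].
#' @return `df`, classed as `localizations`.
#' @export
validate_localizations <- function(df) {
  missing_cols <- setdiff(loc_columns, names(df))
  if (length(missing_cols))
    stop_ct("localization table lacks columns: ",
            paste(missing_cols, collapse = ", "))
  if (nrow(df)) {
    if (!all(is.finite(as.matrix(df[, c("x_nm", "y_nm", "z_nm")]))))
      stop_ct("localization coordinates must be finite")
    if (any(df$psf_photons < 0))
      stop_ct("psf_photons must be >= 0")
    if (any(df$cutout_photons < df$psf_photons))
      stop_ct("cutout_photons must be >= psf_photons")
    if (any(df$lat_prec_nm <= 0) || any(df$ax_prec_nm <= 0))
      stop_ct("precisions must be > 0")
    if (any(df$frame < 0)) stop_ct("frame must be >= 0")
    if (any(df$round < 1)) stop_ct("round must be >= 1")
  }
  class(df) <- unique(c("localizations", class(df)))
  df
}

#' Read / write localization tables (CSV or TSV)
#'
#' The file must carry a header with the required columns
#' (`x_nm, y_nm, z_nm, frame, psf_photons, cutout_photons, z_offset_nm,
#' lat_prec_nm, ax_prec_nm, round`), decimal points, no thousands
#' separators. The separator is inferred from the file extension
#' (`.tsv` = tab, otherwise comma) unless given.
#'
#' @param path file path.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return [read_localizations()] returns a validated localization table.
#' @export
read_localizations <- function(path, sep = NULL) {
  sep <- sep %||% (if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ",")
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  validate_localizations(df)
}

#' @rdname read_localizations
#' @param locs a localization table.
#' @export
write_localizations <- function(locs, path, sep = NULL) {
  sep <- sep %||% (if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ",")
  write.table(locs[, loc_columns], path, sep = sep, row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read / write fiducial marker tables
#'
#' Columns: `marker_id, frame, x_nm, y_nm, z_nm`; one row per marker per
#' frame in which the marker was detected.
#'
#' @param path file path.
#' @return a data frame of fiducial detections.
#' @export
read_fiducials <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("marker_id", "frame", "x_nm", "y_nm", "z_nm")
  if (!all(need %in% names(df)))
    stop_ct("fiducial table needs columns: ", paste(need, collapse = ", "))
  if (!nrow(df)) stop_ct("fiducial table is empty")
  if (!all(is.finite(as.matrix(df[, c("x_nm", "y_nm", "z_nm")]))))
    stop_ct("fiducial positions must be finite")
  df
}

#' @rdname read_fiducials
#' @param fid a fiducial table.
#' @export
write_fiducials <- function(fid, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  write.table(fid, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write BED segment definitions
#'
#' Plain BED4 (chrom, start, end, name), 0-based half-open coordinates.
#'
#' @param path file path.
#' @return data frame with columns `chrom, start, end, name`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)[, 1:4]
  names(df) <- c("chrom", "start", "end", "name")
  if (any(df$end <= df$start)) stop_ct("BED intervals must satisfy end > start")
  df
}

#' @rdname read_bed
#' @param segments a segment data frame (`chrom, start, end, name`).
#' @export
write_bed <- function(segments, path) {
  write.table(segments[, c("chrom", "start", "end", "name")], path,
              sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
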