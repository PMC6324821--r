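# Bead-chain chromatin models at fixed genomic resolution.

#' Bead-chain chromatin model
#'
#' An ordered chain of beads, one per genomic bin of `bin_size` bp, with a
#' hard-sphere radius `r` used by the excluded-volume and clash terms.
#'
#' @param coords numeric matrix (n x 3) of bead centres (nm).
#' @param r bead radius (nm, > 0).
#' @param bin_size genomic bin per bead (bp, default 10000).
#' @param chrom chromosome name.
#' @param start genomic start of the first bead's bin (0-based).
#' @param segment optional segment id.
#' @return an object of class `bead_model`.
#' @export
bead_model <- function(coords, r, bin_size = 10000, chrom = "chr19",
                       start = 0, segment = NA_character_) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop_ct("coords must be n x 3")
  if (!all(is.finite(coords))) stop_ct("bead coordinates must be finite")
  if (r <= 0) stop_ct("bead radius must be > 0")
  structure(list(coords = coords, r = r, bin_size = bin_size, chrom = chrom,
                 start = start, segment = segment),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("bead_model: %d beads @ %g kb, r = %g nm (%s:%d-%d%s)\n",
              nrow(x$coords), x$bin_size / 1000, x$r, x$chrom, x$start,
              x$start + nrow(x$coords) * x$bin_size,
              if (is.na(x$segment)) "" else paste0(", ", x$segment)))
  invisible(x)
}

#' Read / write bead models as whitespace XYZ tables
#'
#' Columns: `bead, chrom, start, x_nm, y_nm, z_nm`, with a header line. The
#' bead radius and bin size are carried in `# r_nm=` / `# bin_bp=` comment
#' lines.
#'
#' @param path file path.
#' @return [read_xyz_model()] returns a `bead_model`.
#' @export
read_xyz_model <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  getnum <- function(key, default) {
    hit <- grep(paste0(key, "="), meta, value = TRUE)
    if (length(hit)) as.numeric(sub(paste0(".*", key, "="), "", hit[1]))
    else default
  }
  df <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE)
  bead_model(as.matrix(df[, c("x_nm", "y_nm", "z_nm")]),
             r = getnum("r_nm", 15),
             bin_size = getnum("bin_bp", 10000),
             chrom = df$chrom[1], start = df$start[1])
}

#' @rdname read_xyz_model
#' @param model a `bead_model`.
#' @export
write_xyz_model <- function(model, path) {
  n <- nrow(model$coords)
  df <- data.frame(bead = seq_len(n), chrom = model$chrom,
                   start = model$start + (seq_len(n) - 1) * model$bin_size,
                   x_nm = model$coords[, 1], y_nm = model$coords[, 2],
                   z_nm = model$coords[, 3])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# r_nm=%g", model$r),
               sprintf("# bin_bp=%g", model$bin_size)), con)
  write.table(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a bead model as a PDB-like file for visualization
#'
#' One CA pseudo-atom per bead (coordinates in nm written as Angstrom
#' fields), consecutive beads CONECTed.
#'
#' @param model a `bead_model`.
#' @param path output path.
#' @export
write_pdb_model <- function(model, path) {
  n <- nrow(model$coords)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n))
    writeLines(sprintf(
      "ATOM  %5d  CA  BEA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      i, i, model$coords[i, 1] / 10, model$coords[i, 2] / 10,
      model$coords[i, 3] / 10), con)
  for (i in seq_len(n - 1))
    writeLines(sprintf("CONECT%5d%5d", i, i + 1), con)
  writeLines("END", con)
  invisible(path)
}

#' Clash score of a bead model
#'
#' Number of serious clashes — unordered non-adjacent bead pairs at distance
#' `d < 2r` — scaled to per-1000-beads: `CLS = clashes * 1000 / n`.
#'
#' @param model a `bead_model` (or an n x 3 coordinate matrix plus `r`).
#' @param r bead radius override (nm).
#' @return the clash score.
#' @export
clash_score <- function(model, r = NULL) {
  if (inherits(model, "bead_model")) {
    coords <- model$coords
    r <- r %||% model$r
  } else coords <- as.matrix(model)
  if (is.null(r) || r <= 0) stop_ct("bead radius must be > 0")
  cpp_clash_count(coords, r) * 1000 / nrow(coords)
}
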