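# Contact matrices and their transformation into spatial restraints.

#' Contact matrix from a conformational ensemble
#'
#' Symmetric matrix of the fraction of models in which each bead pair lies
#' within `cutoff` nm; the diagonal is 1 by construction.
#'
#' @param models list of `bead_model`s (or n x 3 matrices) with identical
#'   bead counts.
#' @param cutoff contact distance in nm.
#' @return an n x n numeric matrix in `[0, 1]`.
#' @export
contacts_from_ensemble <- function(models, cutoff) {
  if (!length(models)) stop_ct("need >= 1 model")
  if (cutoff <= 0) stop_ct("cutoff must be > 0")
  coords <- lapply(models, function(m)
    if (inherits(m, "bead_model")) m$coords else as.matrix(m))
  n <- nrow(coords[[1]])
  if (!all(vapply(coords, nrow, integer(1)) == n))
    stop_ct("inconsistent bead counts across models")
  acc <- matrix(0, n, n)
  for (cc in coords) {
    d <- as.matrix(dist(cc))
    acc <- acc + (d <= cutoff)
  }
  m <- acc / length(models)
  diag(m) <- 1
  m
}

#' Read / write dense contact matrices as TSV
#'
#' Plain dense numeric TSV; the bin size is carried in a `# bin_bp=`
#' comment line.
#'
#' @param path file path.
#' @return [read_contacts()] returns the matrix with attribute `bin_bp`.
#' @export
read_contacts <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  bin <- if (length(meta)) as.numeric(sub(".*bin_bp=", "", meta[1])) else NA
  m <- as.matrix(read.table(text = lines[!startsWith(lines, "#")],
                            sep = "\t"))
  dimnames(m) <- NULL
  attr(m, "bin_bp") <- bin
  m
}

#' @rdname read_contacts
#' @param m contact matrix.
#' @param bin_bp genomic bin size (bp).
#' @export
write_contacts <- function(m, path, bin_bp = 10000) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_bp=%g", bin_bp), con)
  write.table(m, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Spatial restraints from a normalized contact matrix
#'
#' Simplified restraint-based transformation of contact frequencies into
#' harmonic restraints. Log contact frequencies are z-scored within each
#' genomic-distance stratum (|i - j| >= 2); pairs with z at or above
#' `upper_z` receive an upper-bound (attractive) harmonic restraint, pairs
#' at or below `lower_z` a lower-bound (repulsive) one. The equilibrium
#' distance interpolates linearly in z between `2r` (strongest enrichment)
#' and `max_dist` (at the cutoff); adjacent beads always receive
#' connectivity bonds at `d0 = 2r`.
#'
#' @param matrix square symmetric non-negative contact matrix.
#' @param bin_size genomic bin per bead (bp).
#' @param bead_radius bead radius r (nm).
#' @param upper_z,lower_z stratum z-score cutoffs (defaults +0.5 / -0.5).
#' @param max_dist distance scale of the modelled region (nm); default
#'   `2 * bead_radius * sqrt(n)` (random-walk extent).
#' @param k force constant for harmonic restraints (energy/nm^2).
#' @param k_bond force constant for connectivity bonds.
#' @param pseudocount added before the log transform.
#' @return an object of class `restraint_set`: data frame `restraints`
#'   (`i, j, kind, d0_nm, k`; kind in `lower`, `upper`, `bond`) plus fields
#'   `r`, `k_ev`, `n_beads`.
#' @export
restraints_from_contacts <- function(matrix, bin_size = 10000,
                                     bead_radius = 15, upper_z = 0.5,
                                     lower_z = -0.5, max_dist = NULL,
                                     k = 0.01, k_bond = 0.01,
                                     pseudocount = NULL) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop_ct("contact matrix must be square")
  if (max(abs(m - t(m))) > 1e-8 * max(abs(m), 1))
    stop_ct("contact matrix must be symmetric")
  if (any(m < 0)) stop_ct("contact matrix must be non-negative")
  n <- nrow(m)
  max_dist <- max_dist %||% (2 * bead_radius * sqrt(n))
  pseudocount <- pseudocount %||% (min(m[m > 0], na.rm = TRUE) / 10)

  L <- log(m + pseudocount)
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  sep <- pairs[, 2] - pairs[, 1]
  z <- numeric(nrow(pairs))
  for (s in unique(sep[sep >= 2])) {
    sel <- sep == s
    v <- L[pairs[sel, , drop = FALSE]]
    sdv <- sd(v)
    z[sel] <- if (is.na(sdv) || sdv == 0) 0 else (v - mean(v)) / sdv
  }
  zmax <- max(abs(z), upper_z + 1e-9)
  # per-stratum distance anchor: the polymer-expected separation scale
  # 2r * sqrt(s), capped at max_dist; enrichment pulls the equilibrium
  # from the anchor toward contact (2r), depletion pushes it toward
  # max_dist
  anchor <- pmin(2 * bead_radius * sqrt(pmax(sep, 1)), max_dist)

  rows <- list()
  up <- sep >= 2 & z >= upper_z
  if (any(up)) {
    frac <- pmin((z[up] - upper_z) / (zmax - upper_z), 1)
    rows$upper <- data.frame(i = pairs[up, 1], j = pairs[up, 2],
                             kind = "upper",
                             d0_nm = anchor[up] -
                               (anchor[up] - 2 * bead_radius) * frac,
                             k = k)
  }
  lo <- sep >= 2 & z <= lower_z
  if (any(lo)) {
    frac <- pmin((abs(z[lo]) - abs(lower_z)) / (zmax - abs(lower_z)), 1)
    rows$lower <- data.frame(i = pairs[lo, 1], j = pairs[lo, 2],
                             kind = "lower",
                             d0_nm = anchor[lo] +
                               (max_dist - anchor[lo]) * frac,
                             k = k)
  }
  rows$bond <- data.frame(i = seq_len(n - 1), j = 2:n, kind = "bond",
                          d0_nm = 2 * bead_radius, k = k_bond)
  restraints <- do.call(rbind, rows)
  rownames(restraints) <- NULL
  structure(list(restraints = restraints, r = bead_radius, k_ev = k,
                 n_beads = n, bin_size = bin_size),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  tab <- table(x$restraints$kind)
  cat(sprintf("restraint_set: %d beads (r = %g nm); %s\n", x$n_beads, x$r,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Read / write restraint sets as TSV
#'
#' Columns `i, j, kind, d0_nm, k`; bead radius, excluded-volume constant and
#' bead count in `#` header lines.
#'
#' @param path file path.
#' @return [read_restraints()] returns a `restraint_set`.
#' @export
read_restraints <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getnum <- function(key) as.numeric(sub(paste0(".*", key, "="), "",
                                         grep(key, meta, value = TRUE)[1]))
  df <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  structure(list(restraints = df, r = getnum("r_nm"), k_ev = getnum("k_ev"),
                 n_beads = as.integer(getnum("n_beads")),
                 bin_size = getnum("bin_bp")),
            class = "restraint_set")
}

#' @rdname read_restraints
#' @param rs a `restraint_set`.
#' @export
write_restraints <- function(rs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# r_nm=%g", rs$r), sprintf("# k_ev=%g", rs$k_ev),
               sprintf("# n_beads=%d", rs$n_beads),
               sprintf("# bin_bp=%g", rs$bin_size)), con)
  write.table(rs$restraints, con, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

# Integer-coded restraint columns for the C++ energy kernel.
restraint_codes <- function(rs) {
  kind <- match(rs$restraints$kind, c("lower", "upper", "bond"))
  if (anyNA(kind)) stop_ct("unknown restraint kind")
  list(i = as.integer(rs$restraints$i), j = as.integer(rs$restraints$j),
       kind = as.integer(kind), d0 = as.numeric(rs$restraints$d0_nm),
       k = as.numeric(rs$restraints$k))
}
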