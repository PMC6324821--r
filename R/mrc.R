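# Minimal MRC/CCP4 (mode 2, float32) reader/writer for density maps.
# Header layout follows the MRC2014 standard: 1024-byte header, axis order
# X fastest (MAPC/MAPR/MAPS = 1/2/3), voxel size from CELLA / N, origin in
# the ORIGIN fields (nm stored as Angstrom-agnostic floats).

#' Write a density map as MRC/CCP4 (mode 2, float32)
#'
#' @param map a `density_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(map, path) {
  d <- dim(map$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                         # NX NY NZ
  wi(2)                         # MODE 2 = float32
  wi(c(0, 0, 0))                # NXSTART..
  wi(d)                         # MX MY MZ
  wf(d * map$voxel)             # CELLA
  wf(c(90, 90, 90))             # CELLB
  wi(c(1, 2, 3))                # MAPC MAPR MAPS
  wf(c(min(map$data), max(map$data), mean(map$data)))  # DMIN DMAX DMEAN
  wi(1)                         # ISPG
  wi(0)                         # NSYMBT
  wf(if (is.na(map$sigma)) 0 else map$sigma)   # EXTRA word 1: kernel sigma
  wf(if (is.na(map$threshold)) -1 else map$threshold)  # EXTRA word 2
  wi(rep(0, 23))                # EXTRA words 3-25
  wf(map$origin)                # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(sd(as.numeric(map$data)))  # RMS
  wi(0)                         # NLABL
  writeBin(raw(800), con)       # labels
  wf(as.numeric(map$data))      # data, x fastest
  invisible(path)
}

#' Read an MRC/CCP4 density map written by [write_mrc()]
#'
#' Supports mode 2 (float32), axis order X/Y/Z fastest-to-slowest.
#'
#' @param path input file.
#' @return a `density_map`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2L) stop_ct("only MRC mode 2 (float32) is supported")
  ri(3)                         # NXSTART
  m <- ri(3)                    # MX MY MZ
  cella <- rf(3)
  rf(3)                         # CELLB
  mapcrs <- ri(3)
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop_ct("only axis order X,Y,Z (1,2,3) is supported")
  rf(3)                         # DMIN DMAX DMEAN
  ri(2)                         # ISPG NSYMBT
  sigma <- rf(1)
  thr <- rf(1)
  ri(23)                        # remaining EXTRA
  origin <- rf(3)
  readBin(con, "raw", 4)        # "MAP "
  readBin(con, "raw", 4)        # MACHST
  rf(1)                         # RMS
  ri(1)                         # NLABL
  readBin(con, "raw", 800)
  arr <- array(rf(prod(d)), dim = d)
  voxel <- cella[1] / m[1]
  density_map(arr, origin, voxel,
              sigma = if (sigma > 0) sigma else NA_real_,
              threshold = if (thr >= 0) thr else NA_real_)
}
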