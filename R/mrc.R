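# Minimal MRC2014 I/O (mode 2, float32), little-endian, enough to exchange
# 2D images and 3D volumes with the usual structural-biology tools. Only the
# fields the package needs are honoured; the extended header is skipped on
# read and empty on write.

#' Write a grid signal or volume as an MRC file
#'
#' MRC2014, mode 2 (32-bit float), little-endian. 2D images are written with
#' nz = 1. The physical grid step is stored in the cell dimensions.
#'
#' @param x a [grid_signal()], [propeller_volume()], or plain 2D/3D array.
#' @param path output file path.
#' @param spacing grid step stored in the header (taken from `x` when it is
#'   a `grid_signal`).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(x, path, spacing = 1) {
  if (inherits(x, "grid_signal")) {
    spacing <- x$spacing
    a <- x$values
  } else if (inherits(x, "propeller_volume")) {
    a <- x$values
  } else {
    a <- x
  }
  d <- base::dim(a)
  if (is.null(d) || !(length(d) %in% c(2L, 3L))) {
    stop("write_mrc: need a 2D or 3D array")
  }
  if (length(d) == 2L) d <- c(d, 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wi(d)                      # nx, ny, nz
  wi(2L)                     # mode 2: float32
  wi(c(0L, 0L, 0L))          # nxstart..
  wi(d)                      # mx, my, mz
  wf(d * spacing)            # cell dimensions (angstrom-like length units)
  wf(c(90, 90, 90))          # cell angles
  wi(c(1L, 2L, 3L))          # axis order
  wf(c(min(a), max(a), mean(a)))
  wi(c(0L, 0L))              # ispg, nsymbt
  writeBin(raw(100L), con)   # extra
  wf(c(0, 0, 0))             # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(a)))
  wi(0L)                     # nlabl
  writeBin(raw(800L), con)   # labels
  writeBin(as.numeric(a), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRC file written in mode 2
#'
#' @param path MRC file path.
#' @return a [grid_signal()] for 2D/nz = 1 data, otherwise a list with
#'   `values` (3D array) and `spacing`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  d <- ri(3L)
  mode <- ri(1L)
  if (mode != 2L) stop("read_mrc: only mode 2 (float32) is supported")
  ri(3L)           # nxstart
  m <- ri(3L)
  cell <- rf(3L)
  rf(3L)           # angles
  ri(3L)           # axis order
  rf(3L)           # min/max/mean
  ri(1L)           # ispg
  nsymbt <- ri(1L)
  seek(con, 1024L + nsymbt)
  vals <- rf(prod(d))
  spacing <- if (m[1] > 0) cell[1] / m[1] else 1
  if (d[3] == 1L) {
    grid_signal(matrix(vals, d[1], d[2]), spacing = spacing)
  } else {
    list(values = array(vals, d), spacing = spacing)
  }
}
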