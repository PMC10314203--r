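# Container for rotationally averaged third-order invariants: a 3-index
# array over (length, length, angle), used both for the Fourier-space RABS
# and the real-space rabs.

#' Rotationally averaged bispectrum grid
#'
#' @param L1 grid of first vector lengths (k or r).
#' @param L2 grid of second vector lengths (q or s).
#' @param theta grid of in-plane angles between the two vectors, in
#'   (-pi, pi].
#' @param values real array of shape `(|L1|, |L2|, |theta|)`.
#' @param space `"fourier"` (RABS) or `"real"` (rabs).
#' @param meta optional list of provenance (rotation count M, max imaginary
#'   residual, input description).
#' @return object of class `rabs_grid`.
#' @export
rabs_grid <- function(L1, L2, theta, values, space = c("fourier", "real"),
                      meta = list()) {
  space <- match.arg(space)
  values <- array(as.numeric(values), c(length(L1), length(L2), length(theta)))
  if (!all(is.finite(values))) stop("rabs_grid: values must be finite")
  structure(list(L1 = as.numeric(L1), L2 = as.numeric(L2),
                 theta = as.numeric(theta), values = values, space = space,
                 meta = meta), class = "rabs_grid")
}

#' @export
print.rabs_grid <- function(x, ...) {
  cat(sprintf("rabs_grid (%s space): %d x %d x %d (L1 x L2 x theta), max |value| %.4g\n",
              x$space, length(x$L1), length(x$L2), length(x$theta),
              max(abs(x$values))))
  invisible(x)
}

#' Mirror map on a RABS/rabs grid
#'
#' Re-indexes the angle axis theta -> -theta. For the third-order invariant
#' of a 2D signal this is exactly the effect of mirroring the signal, so
#' applying `mirror_map` to the invariant of an image reproduces the
#' invariant of the mirrored image. The map is an involution. The theta grid
#' must be closed under negation (theta = pi is identified with -pi).
#'
#' @param rg a [rabs_grid()].
#' @return the mirrored `rabs_grid`.
#' @export
mirror_map <- function(rg) {
  stopifnot(inherits(rg, "rabs_grid"))
  th <- rg$theta
  wrap <- function(a) ((a + pi) %% (2 * pi)) - pi
  target <- wrap(-th)
  idx <- vapply(target, function(a) {
    j <- which(abs(wrap(th - a)) < 1e-9)
    if (length(j) != 1L) NA_integer_ else j
  }, integer(1))
  if (anyNA(idx)) {
    stop("mirror_map: theta grid is not symmetric about 0 (no -theta partner)")
  }
  out <- rg
  out$values <- rg$values[, , idx, drop = FALSE]
  out
}

#' Write / read a RABS grid as a JSON container
#'
#' Single-file container with the three axis vectors, the flattened value
#' array and provenance metadata.
#'
#' @param rg a [rabs_grid()].
#' @param path output path.
#' @return `write_rabs_json` returns `path` invisibly; `read_rabs_json`
#'   returns a `rabs_grid`.
#' @export
write_rabs_json <- function(rg, path) {
  stopifnot(inherits(rg, "rabs_grid"))
  jsonlite::write_json(
    list(L1 = rg$L1, L2 = rg$L2, theta = rg$theta,
         values = as.numeric(rg$values), space = rg$space, meta = rg$meta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rabs_json
#' @export
read_rabs_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rabs_grid(x$L1, x$L2, x$theta, x$values, space = x$space,
            meta = as.list(x$meta))
}
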