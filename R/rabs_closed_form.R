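# Closed-form rotationally averaged three-point function of a 2D Gaussian
# mixture, in symmetric triangle coordinates.
#
# Derivation (performed from scratch; the constants below follow from it and
# are locked by the grid-oracle agreement tests).
#
# For f = sum_j a_j g(x - c_j), g a normalised Gaussian of width R, the
# three-point function is a sum over ordered index triples (j1, j2, j3) of
# integrals of three-Gaussian products. Completing the square,
#   Int g(t - mu1) g(t - mu2) g(t - mu3) dt
#     = (2 pi R^2)^(-2) 3^(-1) exp(-(|mu1-mu2|^2+|mu2-mu3|^2+|mu3-mu1|^2)/(6R^2))
# in two dimensions. With mu1 = c_j1, mu2 = c_j2 - r, mu3 = c_j3 - s and the
# probe pair (r, s) rotated by phi, the exponent is C0 - L(phi) with
#   C0 = (sum of pattern side^2) + (r^2 + s^2 + |r-s|^2),
#   L(phi) = 2 W cos(phi + psi),
# a single sinusoid whose amplitude W couples the probe and pattern
# triangles. The rotational mean of exp(L(phi)/(6R^2)) is a Bessel I0, so
#   rabs = (1/(3 (2 pi R^2)^2)) sum_triples a_j1 a_j2 a_j3
#            exp(-(C0 - 2W)/(6R^2)) Ihat0(W/(3R^2))            (exact).
# Changing to the symmetric variables (probe and pattern treated alike)
#   drop  = (3^(3/4)/sqrt(2)) |O - vertex|,   a_v at the pattern triangle,
#   short = (3^(1/4)/sqrt(2)) |side|,         a_w at the pattern triangle,
# diagonalises both quadratic forms:
#   C0 = sqrt(3) (v^2 + w^2 + a_v^2 + a_w^2),
#   W  = sqrt(3) sqrt(v^2 a_v^2 + w^2 a_w^2
#                     + 2 v w a_v a_w cos(theta - theta_T)),
# with theta_T the pattern triangle's signed angle. Near a peak this is a
# product of two 1D Gaussians of width 3^(1/4) R centred at (a_v, a_w)
# times an angular factor - the separable structure the symmetric
# coordinates exist to expose. Mirroring the pattern negates every theta_T,
# so the whole landscape maps theta -> -theta.

#' Closed-form rabs of a Gaussian mixture in triangle coordinates
#'
#' Evaluates the exact rotationally averaged three-point function of a 2D
#' Gaussian-mixture pattern at the symmetric triangle coordinates
#' `(v, w, theta)` = (drop, short side, signed angle). For small Gaussian
#' width the landscape is a set of bumps, one per (ordered) triangle of the
#' pattern, centred at the triangles' own coordinates; mirroring the
#' pattern negates the angle axis pointwise.
#'
#' @param p a 2D [point_pattern()].
#' @param v drop-coordinate values (vectorised; recycled against `w`,
#'   `theta`).
#' @param w short-side-coordinate values.
#' @param theta signed-angle values.
#' @param cross_only drop terms with a repeated atom index. Those "self"
#'   terms are the third-order analogue of the uninformative self terms of
#'   the second-order closed forms: they pile up on ridges along `w = 0`
#'   and `v = 0` that carry no information about the atoms' arrangement,
#'   and for patterns containing close pairs they can tower over genuine
#'   thin-triangle resonances. Default `FALSE` (full sum).
#' @return numeric vector of rabs values.
#' @export
rabs_closed_form <- function(p, v, w, theta, cross_only = FALSE) {
  stopifnot(inherits(p, "point_pattern"))
  if (p$dim != 2L) stop("rabs_closed_form: closed form implemented for D = 2")
  nmax <- max(length(v), length(w), length(theta))
  v <- rep_len(as.numeric(v), nmax)
  w <- rep_len(as.numeric(w), nmax)
  theta <- rep_len(as.numeric(theta), nmax)
  R2 <- p$R^2
  N <- nrow(p$centers)
  if (N == 0L) return(numeric(nmax))
  out <- numeric(nmax)
  pref <- 1 / (3 * (2 * pi * R2)^2)
  cs <- p$centers
  amp <- p$amplitudes
  idx <- seq_len(N)
  for (j1 in idx) for (j2 in idx) for (j3 in idx) {
    if (cross_only && (j1 == j2 || j2 == j3 || j1 == j3)) next
    Ot <- (cs[j1, ] + cs[j2, ] + cs[j3, ]) / 3
    av_vec <- DROP_SCALE * (Ot - cs[j1, ])
    aw_vec <- SHORT_SCALE * (cs[j3, ] - cs[j2, ])
    a_v <- sqrt(sum(av_vec^2))
    a_w <- sqrt(sum(aw_vec^2))
    th_T <- signed_angle(aw_vec, av_vec)
    C0 <- sqrt(3) * (v^2 + w^2 + a_v^2 + a_w^2)
    W <- sqrt(3) * sqrt(pmax(v^2 * a_v^2 + w^2 * a_w^2 +
                               2 * v * w * a_v * a_w * cos(theta - th_T), 0))
    out <- out + amp[j1] * amp[j2] * amp[j3] *
      exp(-(C0 - 2 * W) / (6 * R2)) * i0_hat(W / (3 * R2))
  }
  pref * out
}

#' Closed-form rabs evaluated on a coordinate grid
#'
#' Convenience wrapper building a [rabs_grid()] (axes: drop, short, angle)
#' from [rabs_closed_form()].
#'
#' @param p a 2D [point_pattern()].
#' @param v_grid,w_grid,theta_grid coordinate axes.
#' @return a [rabs_grid()] with `space = "real"`; note the axes are the
#'   symmetric triangle coordinates, not raw offset lengths.
#' @export
rabs_closed_form_grid <- function(p, v_grid, w_grid, theta_grid) {
  gg <- expand.grid(v = v_grid, w = w_grid, theta = theta_grid,
                    KEEP.OUT.ATTRS = FALSE)
  vals <- rabs_closed_form(p, gg$v, gg$w, gg$theta)
  rabs_grid(v_grid, w_grid, theta_grid, vals, space = "real",
            meta = list(coordinates = "triangle(v,w,theta)"))
}
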