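# Third-order motion invariants of 2D signals: the bispectrum, its
# rotational average (RABS) computed from the Fourier side, the real-space
# rotationally averaged three-point function (rabs), and the Bessel kernel
# that transforms rabs into RABS.
#
# Derivation of the transform (recorded because the result is used as the
# package's normalisation): with F(k) = Int f(r) e^{+ik.r} dr,
#   B(kv, qv) = F(kv) F(qv) F(-kv-qv) = Int dr ds e^{i(kv.r + qv.s)} b(r, s),
#   b(r, s) = Int dt f(t) f(t+r) f(t+s).
# Averaging B over simultaneous rotation of (kv, qv) (plain mean over the
# rotation angle) and writing the double area integral in polar form gives
#   RABS(k, q, th_qk) =
#     2 pi Int r dr s ds dth_sr J0(sqrt(arg)) rabs(r, s, th_sr),
#   arg = k^2 r^2 + q^2 s^2 + 2 (kv.qv)(rv.sv) + 2 (kv x qv).(rv x sv)
#       = k^2 r^2 + q^2 s^2 + 2 k q r s cos(th_qk - th_sr),
# where rabs is the plain rotational mean of b. The cross-product term is
# the one that changes sign under mirroring, so the kernel commutes with the
# theta -> -theta mirror map.

# wavevectors for a (length, length, angle) grid at M rotation angles
rotation_angles <- function(M) 2 * pi * (seq_len(M) - 1L) / M

#' Bispectrum of a 2D signal at one wavevector pair
#'
#' `B(k, q) = F(k) F(q) F(-k-q)`: the product of three spectrum values at
#' wavevectors summing to zero, which is what makes it translation
#' invariant. Off-grid wavevectors are evaluated by exact trigonometric
#' interpolation (a direct Fourier sum over the sampled signal), so the
#' translation phases cancel to machine precision.
#'
#' @param f a 2D [grid_signal()] (or a `fourier_signal`, inverted
#'   internally).
#' @param k,q numeric 2-vectors; `k`, `q` and `k+q` must lie within the
#'   Nyquist band.
#' @return a complex scalar (real and positive for a centred Gaussian).
#' @export
bispectrum <- function(f, k, q) {
  if (inherits(f, "fourier_signal")) f <- inverse_fourier(f)
  stopifnot(inherits(f, "grid_signal"), f$dim == 2L)
  kn <- nyquist_k(f$spacing)
  lens <- sqrt(c(sum(k^2), sum(q^2), sum((k + q)^2)))
  if (any(lens > kn + 1e-12)) {
    stop("bispectrum: a wavevector lies outside the sampled band")
  }
  K <- rbind(k, q, -(k + q))
  Fv <- eval_fourier_at(f, K)
  Fv[1] * Fv[2] * Fv[3]
}

#' Rotationally averaged bispectrum (Fourier route)
#'
#' For each (k, q, theta) cell, averages `B(R_phi k, R_phi q)` over M
#' equally spaced rotation angles phi, with |k|, |q| fixed and `theta` the
#' signed angle from the first to the second wavevector (counterclockwise
#' positive). For a real input the imaginary parts are discarded; their
#' largest modulus relative to the peak is recorded in `meta$max_imag`.
#'
#' @param f a 2D [grid_signal()] (or `fourier_signal`).
#' @param k_len,q_len grids of wavevector lengths.
#' @param theta grid of angles in (-pi, pi]; defaults to 16 uniform angles
#'   closed under negation.
#' @param M number of rotation angles (default 256).
#' @return a [rabs_grid()] with `space = "fourier"`.
#' @export
rabs_fourier <- function(f, k_len, q_len = k_len, theta = NULL, M = 256L) {
  if (inherits(f, "fourier_signal")) f <- inverse_fourier(f)
  stopifnot(inherits(f, "grid_signal"), f$dim == 2L)
  if (is.null(theta)) theta <- uniform_theta_grid(16L)
  kn <- nyquist_k(f$spacing)
  # third-vector length for every (k, q, theta): sqrt(k^2+q^2+2kq cos th)
  third_max <- max(sqrt(pmax(0, outer(outer(k_len^2, q_len^2, `+`),
                                      rep(1, length(theta))) +
                               2 * outer(outer(k_len, q_len), cos(theta)))))
  if (max(k_len, q_len, third_max) > kn + 1e-12) {
    stop("rabs_fourier: grid extends outside the sampled band")
  }
  phi <- rotation_angles(M)
  nk <- length(k_len); nq <- length(q_len); nt <- length(theta)

  # F on the two rings of first/second vectors
  Kk <- cbind(rep(k_len, each = M) * cos(phi), rep(k_len, each = M) * sin(phi))
  Fk <- matrix(eval_fourier_at(f, Kk), nrow = M)            # M x nk
  ang_q <- outer(phi, theta, `+`)                           # M x nt
  Kq <- cbind(rep(q_len, each = M * nt) * cos(as.numeric(ang_q)),
              rep(q_len, each = M * nt) * sin(as.numeric(ang_q)))
  Fq <- array(eval_fourier_at(f, Kq), c(M, nt, nq))         # phi x theta x q

  vals <- array(0, c(nk, nq, nt))
  imax <- 0
  for (a in seq_len(nk)) {
    kx <- k_len[a] * cos(phi); ky <- k_len[a] * sin(phi)
    for (c in seq_len(nt)) {
      qang <- phi + theta[c]
      for (b in seq_len(nq)) {
        qx <- q_len[b] * cos(qang); qy <- q_len[b] * sin(qang)
        F3 <- eval_fourier_at(f, cbind(-(kx + qx), -(ky + qy)))
        Bv <- Fk[, a] * Fq[, c, b] * F3
        m <- mean(Bv)
        imax <- max(imax, abs(Im(m)))
        vals[a, b, c] <- Re(m)
      }
    }
  }
  rabs_grid(k_len, q_len, theta, vals, space = "fourier",
            meta = list(M = M, max_imag = imax))
}

#' Uniform angle grid closed under negation
#'
#' `n` equally spaced angles over (-pi, pi] (with pi and -pi identified),
#' containing `-t` for every grid angle `t` — the grid [mirror_map()]
#' requires. `n` must be even.
#'
#' @param n number of angles (even).
#' @return numeric vector of angles.
#' @export
uniform_theta_grid <- function(n) {
  stopifnot(n %% 2L == 0L)
  seq(-pi, pi, length.out = n + 1L)[-1L]
}

#' Transform kernel between real- and Fourier-space third-order invariants
#'
#' `J0(sqrt(k^2 r^2 + q^2 s^2 + 2 k q r s cos(theta_qk - theta_sr)))`: the
#' joint rotational average of `exp(i(k.r' + q.s'))` over simultaneous
#' rotations of the real-space pair. The angular dependence enters only
#' through `theta_qk - theta_sr`, so flipping the sign of the Fourier-side
#' angle is exactly equivalent to flipping the real-side angle: the
#' cross-product part of the argument is the mirror-sign carrier. The
#' argument of the square root is clipped at zero against roundoff.
#'
#' @param k,q Fourier-side vector lengths (nonnegative).
#' @param theta_qk signed angle from the k to the q vector.
#' @param r,s real-side vector lengths (nonnegative).
#' @param theta_sr signed angle from the r to the s vector.
#' @return kernel values (vectorised over any argument).
#' @export
rabs_kernel <- function(k, q, theta_qk, r, s, theta_sr) {
  if (any(c(k, q, r, s) < 0)) stop("rabs_kernel: lengths must be nonnegative")
  arg <- k^2 * r^2 + q^2 * s^2 + 2 * k * q * r * s * cos(theta_qk - theta_sr)
  besselJ(sqrt(pmax(arg, 0)), 0)
}

#' Rotationally averaged real-space three-point function (rabs)
#'
#' Computes `b(r, s) = Int f(t) f(t+r) f(t+s) dt` for all integer offset
#' pairs through FFT cross-correlations, then averages over M simultaneous
#' rotations of the offset pair `(r, s)` with separable bilinear
#' interpolation of the 4-index b array at the rotated (generally off-grid)
#' offsets. When the requested lengths are integer multiples of the grid
#' spacing and `M = 4`, every rotated offset is an exact grid point and the
#' result matches a direct triple-loop sum exactly.
#'
#' @param f a 2D [grid_signal()].
#' @param r_len,s_len grids of offset lengths (length units).
#' @param theta angle grid in (-pi, pi]; default 16 uniform angles.
#' @param M number of rotation angles (default 64).
#' @return a [rabs_grid()] with `space = "real"`.
#' @export
rabs_real <- function(f, r_len, s_len = r_len, theta = NULL, M = 64L) {
  stopifnot(inherits(f, "grid_signal"), f$dim == 2L)
  if (is.null(theta)) theta <- uniform_theta_grid(16L)
  n <- base::dim(f$values)[1]
  v <- f$values
  # b4[ri, rj, si, sj]: b at integer offsets (FFT order along each axis)
  FT <- stats::fft(v)
  b4 <- array(0, c(n, n, n, n))
  for (rj in seq_len(n)) {
    for (ri in seq_len(n)) {
      g <- v * shift_array(v, -c(ri - 1L, rj - 1L))   # f(t) f(t + r)
      # cross-correlation with f: sum_t g(t) f(t + s) for all integer s
      b4[ri, rj, , ] <- Re(stats::fft(Conj(stats::fft(g)) * FT,
                                      inverse = TRUE)) / n^2
    }
  }
  b4 <- b4 * f$spacing^2
  phi <- rotation_angles(M)
  nr <- length(r_len); ns <- length(s_len); nt <- length(theta)
  vals <- array(0, c(nr, ns, nt))
  wrap_idx <- function(x) (x %% n) + 1L   # voxel offsets in FFT order
  for (a in seq_len(nr)) {
    rx <- r_len[a] * cos(phi) / f$spacing
    ry <- r_len[a] * sin(phi) / f$spacing
    r0x <- floor(rx); r0y <- floor(ry)
    fx <- rx - r0x; fy <- ry - r0y
    for (c in seq_len(nt)) {
      sang <- phi + theta[c]
      for (b in seq_len(ns)) {
        sx <- s_len[b] * cos(sang) / f$spacing
        sy <- s_len[b] * sin(sang) / f$spacing
        s0x <- floor(sx); s0y <- floor(sy)
        gx <- sx - s0x; gy <- sy - s0y
        acc <- 0
        for (dr in 0:3) {
          wrx <- if (dr %% 2L) fx else 1 - fx
          wry <- if (dr >= 2L) fy else 1 - fy
          irx <- wrap_idx(r0x + dr %% 2L)
          iry <- wrap_idx(r0y + (dr >= 2L))
          for (ds in 0:3) {
            wsx <- if (ds %% 2L) gx else 1 - gx
            wsy <- if (ds >= 2L) gy else 1 - gy
            isx <- wrap_idx(s0x + ds %% 2L)
            isy <- wrap_idx(s0y + (ds >= 2L))
            w <- wrx * wry * wsx * wsy
            acc <- acc + sum(w * b4[cbind(irx, iry, isx, isy)])
          }
        }
        vals[a, b, c] <- acc / M
      }
    }
  }
  rabs_grid(r_len, s_len, theta, vals, space = "real", meta = list(M = M))
}

#' Transform a real-space rabs grid to the Fourier-space RABS
#'
#' Weighted quadrature of the rabs grid against [rabs_kernel()] with measure
#' `r s dr ds dtheta` and overall constant `2 pi` (see the derivation at the
#' top of the source file): trapezoid in the two lengths, rectangle rule on
#' the periodic angle grid. The real-space grid should cover the support of
#' rabs; a non-decayed boundary triggers a truncation warning recorded in
#' `meta$tail_truncated`.
#'
#' @param rg a [rabs_grid()] with `space = "real"` whose theta grid covers
#'   (-pi, pi] uniformly.
#' @param k_len,q_len,theta_out output Fourier-side grids (defaults: the
#'   input theta grid for `theta_out`).
#' @return a [rabs_grid()] with `space = "fourier"`.
#' @export
rabs_real_to_fourier <- function(rg, k_len, q_len = k_len, theta_out = NULL) {
  stopifnot(inherits(rg, "rabs_grid"))
  if (rg$space != "real") stop("rabs_real_to_fourier: input must be real-space")
  if (is.null(theta_out)) theta_out <- rg$theta
  mx <- max(abs(rg$values))
  edge <- max(abs(rg$values[length(rg$L1), , ]), abs(rg$values[, length(rg$L2), ]))
  truncated <- FALSE
  if (mx > 0 && edge > 1e-3 * mx) {
    warning("rabs_real_to_fourier: rabs has not decayed at the grid boundary",
            call. = FALSE)
    truncated <- TRUE
  }
  trap <- function(x) {
    w <- diff(x)
    c(w[1] / 2, (w[-1] + w[-length(w)]) / 2, w[length(w)] / 2)
  }
  wr <- trap(rg$L1) * rg$L1
  ws <- trap(rg$L2) * rg$L2
  dth <- 2 * pi / length(rg$theta)
  nk <- length(k_len); nq <- length(q_len); nto <- length(theta_out)
  vals <- array(0, c(nk, nq, nto))
  for (a in seq_len(nk)) {
    for (b in seq_len(nq)) {
      # kernel over (r, s, th_sr) for each output theta
      kr <- outer(k_len[a] * rg$L1, q_len[b] * rg$L2,
                  function(xx, yy) xx^2 + yy^2)
      cross <- 2 * k_len[a] * q_len[b] * outer(rg$L1, rg$L2)
      for (c in seq_len(nto)) {
        acc <- 0
        for (it in seq_along(rg$theta)) {
          kerm <- besselJ(sqrt(pmax(kr + cross *
                                      cos(theta_out[c] - rg$theta[it]), 0)), 0)
          acc <- acc + sum((wr %o% ws) * kerm * rg$values[, , it])
        }
        vals[a, b, c] <- 2 * pi * acc * dth
      }
    }
  }
  rabs_grid(k_len, q_len, theta_out, vals, space = "fourier",
            meta = list(from = "rabs_real_to_fourier",
                        tail_truncated = truncated))
}
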