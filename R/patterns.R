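# Synthetic signal generators: Gaussian mixtures on grids, Bessel ring and
# angular-harmonic patterns, and noisy "propeller" volumes. These are the
# fixtures every invariant in the package is exercised against.

#' Rasterise a point pattern onto a regular grid
#'
#' Samples the sum of isotropic normalised Gaussians (total mass = amplitude,
#' peak value amplitude / (2*pi*R^2)^(D/2)) at the grid nodes.
#'
#' @param pattern a [point_pattern()] (2D or 3D).
#' @param n grid size per axis.
#' @param spacing grid step (length units).
#' @return a [grid_signal()].
#' @export
rasterize <- function(pattern, n, spacing = 1) {
  stopifnot(inherits(pattern, "point_pattern"))
  n <- as.integer(n)
  D <- pattern$dim
  half_lo <- -(floor(n / 2)) * spacing
  half_hi <- (n - 1 - floor(n / 2)) * spacing
  if (nrow(pattern$centers) > 0L) {
    bad <- which(apply(pattern$centers, 1L, function(a)
      any(a < half_lo) || any(a > half_hi)))
    if (length(bad)) {
      stop(sprintf("rasterize: center %d at (%s) falls outside the box [%g, %g]",
                   bad[1], paste(signif(pattern$centers[bad[1], ], 4),
                                 collapse = ", "), half_lo, half_hi))
    }
  }
  ax <- (seq_len(n) - (floor(n / 2) + 1L)) * spacing
  norm <- 1 / (2 * pi * pattern$R^2)^(D / 2)
  gauss1d <- function(a) exp(-(ax - a)^2 / (2 * pattern$R^2))
  if (D == 2L) {
    vals <- matrix(0, n, n)
    for (j in seq_len(nrow(pattern$centers))) {
      vals <- vals + pattern$amplitudes[j] * norm *
        outer(gauss1d(pattern$centers[j, 1]), gauss1d(pattern$centers[j, 2]))
    }
  } else {
    vals <- array(0, c(n, n, n))
    for (j in seq_len(nrow(pattern$centers))) {
      gx <- gauss1d(pattern$centers[j, 1])
      gy <- gauss1d(pattern$centers[j, 2])
      gz <- gauss1d(pattern$centers[j, 3])
      vals <- vals + pattern$amplitudes[j] * norm *
        outer(outer(gx, gy), gz)
    }
  }
  grid_signal(vals, spacing = spacing)
}

# raised-cosine apodisation over the outer `frac` of the box radius; the
# ring/harmonic patterns decay only like r^(-1/2), so truncating them at the
# box edge without tapering would ring badly in Fourier space.
apodize_radius <- function(r, rmax, frac = 0.1) {
  r0 <- (1 - frac) * rmax
  w <- rep(1, length(r))
  mid <- r > r0 & r < rmax
  w[mid] <- 0.5 * (1 + cos(pi * (r[mid] - r0) / (rmax - r0)))
  w[r >= rmax] <- 0
  w
}

#' Bessel ring pattern
#'
#' The 2D signal `f(r) = J0(r / R)`, whose Fourier transform is concentrated
#' on the ring |k| = 1/R. Sampled on a centred grid and tapered by a
#' raised-cosine edge apodisation over the outer 10% of the box radius.
#' The sampled field is recentred to exactly zero mean: the ideal ring
#' spectrum vanishes at k = 0, and the small net mass left by truncating
#' the slowly decaying Bessel tail at the box edge is a discretisation
#' artifact (it shifts the value at the origin from J0(0) = 1 by a few
#' parts per thousand at typical grid sizes).
#' The only wavevector triangles this pattern supports in its bispectrum are
#' equilateral ones on that ring, so its rotationally averaged bispectrum is
#' concentrated at a single point.
#'
#' @param R ring scale: the Fourier ring sits at radius `1/R`.
#' @param n grid size.
#' @param spacing grid step; `1/R` must lie below the Nyquist wavenumber
#'   `pi/spacing`.
#' @return a [grid_signal()].
#' @export
ring_pattern <- function(R, n, spacing = 1) {
  if (1 / R >= nyquist_k(spacing)) {
    stop("ring_pattern: Fourier ring 1/R is at or above the Nyquist wavenumber")
  }
  n <- as.integer(n)
  ax <- (seq_len(n) - (floor(n / 2) + 1L)) * spacing
  r <- sqrt(outer(ax^2, ax^2, `+`))
  vals <- besselJ(r / R, 0) * apodize_radius(r, rmax = (n / 2) * spacing)
  grid_signal(vals - mean(vals), spacing = spacing)
}

#' Angular-harmonic Bessel pattern
#'
#' The 2D signal `f(r, theta) = cos(2 m theta) * J_{2m}(r / R)`: a single
#' angular Fourier harmonic supported on the same Fourier ring as
#' [ring_pattern()]. For every integer `m >= 1` its rotationally averaged
#' bispectrum vanishes identically (the three-fold angular integral of a
#' single harmonic has no zero-frequency component), which is the standard
#' example of distinct patterns that third-order invariants cannot separate.
#'
#' @inheritParams ring_pattern
#' @param m harmonic index, integer `>= 1`; the pattern oscillates with
#'   angular frequency `2m` around any centred circle.
#' @return a [grid_signal()].
#' @export
harmonic_pattern <- function(m, R, n, spacing = 1) {
  m <- as.integer(m)
  if (m < 1L) stop("harmonic_pattern: m must be a positive integer")
  if (1 / R >= nyquist_k(spacing)) {
    stop("harmonic_pattern: Fourier ring 1/R is at or above the Nyquist wavenumber")
  }
  n <- as.integer(n)
  ax <- (seq_len(n) - (floor(n / 2) + 1L)) * spacing
  xx <- outer(ax, rep(1, n))
  yy <- outer(rep(1, n), ax)
  r <- sqrt(xx^2 + yy^2)
  th <- atan2(yy, xx)
  vals <- cos(2 * m * th) * besselJ(r / R, 2 * m) *
    apodize_radius(r, rmax = (n / 2) * spacing)
  grid_signal(vals, spacing = spacing)
}

# round half away from grid-dependence: plain floor(x + 0.5) so results do
# not depend on R's round-half-to-even rule
round_half_up <- function(x) floor(x + 0.5)

#' The 24 rotation matrices of the cubic group
#'
#' All proper rotations mapping the coordinate axes onto signed axes:
#' the signed permutation matrices with determinant +1.
#'
#' @return list of 24 orthogonal 3x3 matrices (determinant +1).
#' @export
cubic_rotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- vector("list", 24L)
  k <- 0L
  for (p in perms) {
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      m <- matrix(0, 3, 3)
      m[cbind(1:3, p)] <- c(s1, s2, s3)
      if (abs(det(m) - 1) < 1e-12) {
        k <- k + 1L
        out[[k]] <- m
      }
    }
  }
  out
}

#' Jumble of noisy four-point helical "propellers" in a cubic volume
#'
#' Builds the chirality test volume: each copy is the four-point single-turn
#' helix stencil of [helix_probe()] (quarter-turn azimuthal steps, quarter
#' pitch height steps at radius `radius` about the z axis), placed at a
#' uniformly random integer translation and one of the 24 cubic-group
#' rotations, its voxels set to unit value. Independent Gaussian noise of
#' standard deviation `noise_sigma` is then added to every voxel.
#'
#' @param n_copies number of inserted propellers.
#' @param box cubic box edge length in voxels.
#' @param radius helix radius in voxels.
#' @param pitch helix pitch (one full turn) in voxels; its sign selects the
#'   handedness.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param seed mandatory RNG seed; the same seed reproduces the volume
#'   bit-exactly.
#' @return object of class `propeller_volume`: a [grid_signal()]-like list
#'   with `values` (box^3 array), plus `truth` (radius, pitch, n_copies,
#'   noise_sigma, seed, placements) and `collisions`, the number of stencil
#'   points that landed on an already-occupied voxel.
#' @export
propeller_volume <- function(n_copies = 100L, box = 32L, radius = 3,
                             pitch = 8, noise_sigma = 0.45, seed) {
  if (missing(seed)) stop("propeller_volume: seed is required")
  n_copies <- as.integer(n_copies)
  box <- as.integer(box)
  probe <- helix_probe(radius, pitch)
  rots <- cubic_rotations()
  # integer offsets for every orientation; reject if the probe cannot fit
  offs <- lapply(rots, function(Rm) round_half_up(probe %*% t(Rm)))
  span <- range(unlist(offs))
  if (span[2] - span[1] + 1 > box) {
    stop("propeller_volume: rotated probe does not fit in the box")
  }
  set.seed(seed)
  vol <- array(0, c(box, box, box))
  placements <- matrix(0L, n_copies, 4L,
                       dimnames = list(NULL, c("x", "y", "z", "orientation")))
  collisions <- 0L
  for (cidx in seq_len(n_copies)) {
    oidx <- sample.int(24L, 1L)
    d <- offs[[oidx]]
    lo <- apply(d, 2L, min)
    hi <- apply(d, 2L, max)
    # uniform over centre positions keeping all four points inside the box
    pos <- vapply(1:3, function(ax) {
      sample.int(box - (hi[ax] - lo[ax]), 1L) - 1L - lo[ax]
    }, numeric(1))
    pos <- as.integer(pos)
    vox <- sweep(d, 2L, pos, `+`) + 1L  # 1-based voxel indices
    for (r in seq_len(4L)) {
      if (vol[vox[r, 1], vox[r, 2], vox[r, 3]] != 0) collisions <- collisions + 1L
      vol[vox[r, 1], vox[r, 2], vox[r, 3]] <- 1
    }
    placements[cidx, ] <- c(pos, oidx)
  }
  if (noise_sigma > 0) {
    vol <- vol + array(stats::rnorm(box^3, sd = noise_sigma), c(box, box, box))
  }
  structure(list(values = vol, box = box,
                 truth = list(radius = radius, pitch = pitch,
                              n_copies = n_copies, noise_sigma = noise_sigma,
                              seed = seed, placements = placements),
                 collisions = collisions),
            class = "propeller_volume")
}

#' @export
print.propeller_volume <- function(x, ...) {
  cat(sprintf(paste0("propeller_volume: %d^3 voxels, %d copies (radius %g,",
                     " pitch %g), noise sd %g, %d collision(s)\n"),
              x$box, x$truth$n_copies, x$truth$radius, x$truth$pitch,
              x$truth$noise_sigma, x$collisions))
  invisible(x)
}
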