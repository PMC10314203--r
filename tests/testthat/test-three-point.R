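test_that("bispectrum is translation invariant and matches Gaussian values", {
  p <- point_pattern(rbind(c(0, 0)), R = 1)
  g <- rasterize(p, 64, 0.25)
  k <- c(0.8, 0.3); q <- c(-0.2, 0.5)
  B <- bispectrum(g, k, q)
  expect_equal(Im(B), 0, tolerance = 1e-12)
  expect_equal(Re(B), exp(-(sum(k^2) + sum(q^2) + sum((k + q)^2)) / 2),
               tolerance = 1e-6)
  expect_gt(Re(B), 0)

  # B(0,0) is the cubed total mass
  expect_equal(Re(bispectrum(g, c(0, 0), c(0, 0))),
               (sum(g$values) * 0.25^2)^3, tolerance = 1e-10)

  # translation invariance at an incommensurate wavevector pair
  p3 <- random_pattern(3, R = 0.4, seed = 21)
  g3 <- rasterize(p3, 64, 0.25)
  B1 <- bispectrum(g3, k, q)
  B2 <- bispectrum(translate_signal(g3, c(4, -6)), k, q)
  expect_lt(abs(B1 - B2) / abs(B1), 1e-8)

  expect_error(bispectrum(g, c(20, 0), c(0, 0)), "band")
})

test_that("rabs kernel reduces correctly and matches its Monte-Carlo average", {
  # mirror flip on either side is the same kernel value
  ks <- c(0.9, 1.4); th <- 0.7; rs <- c(1.1, 0.8); tsr <- -1.2
  expect_equal(rabs_kernel(ks[1], ks[2], -th, rs[1], rs[2], tsr),
               rabs_kernel(ks[1], ks[2], th, rs[1], rs[2], -tsr))
  # q = 0 or s = 0 removes the angular dependence
  expect_equal(rabs_kernel(1, 0, 0.4, 1.3, 2, 1.1),
               besselJ(sqrt(1.3^2), 0))
  expect_equal(rabs_kernel(1.2, 2, 0.4, 1.3, 0, 1.1),
               besselJ(1.2 * 1.3, 0))
  # Monte-Carlo oracle: joint random rotation of the real-space pair
  set.seed(31)
  nmc <- 2e5
  k <- 1.1; q <- 0.7; thqk <- 1.9; r <- 1.3; s <- 0.9; thsr <- -0.6
  phi <- stats::runif(nmc, 0, 2 * pi)
  # k vec at angle 0, q vec at angle thqk; the pair (r, s) jointly rotated
  val <- cos(k * r * cos(phi) + q * s * cos(phi + thsr - thqk))
  se <- stats::sd(val) / sqrt(nmc)
  expect_lt(abs(rabs_kernel(k, q, thqk, r, s, thsr) - mean(val)), 3 * se)
})

test_that("rabs_real reproduces a brute-force triple sum and translation", {
  set.seed(3)
  v <- matrix(runif(64), 8, 8)
  g <- grid_signal(v, spacing = 1)
  rl <- c(1, 2)
  th <- uniform_theta_grid(4)
  rg <- rabs_real(g, rl, rl, th, M = 4)
  for (a in 1:2) for (b in 1:2) for (cc in 1:4) {
    acc <- 0
    for (m in 0:3) {
      rv <- rot90_vec(c(rl[a], 0), m)
      sv <- rot90_vec(round(c(rl[b] * cos(th[cc]), rl[b] * sin(th[cc]))), m)
      acc <- acc + brute_b(v, rv, sv)
    }
    expect_equal(rg$values[a, b, cc], acc / 4, tolerance = 1e-8)
  }
  rg2 <- rabs_real(translate_signal(g, c(3, 2)), rl, rl, th, M = 4)
  expect_lt(max(abs(rg2$values - rg$values)), 1e-10 * max(abs(rg$values)))
})

test_that("ring pattern RABS peaks at the closing equilateral wavevector triple", {
  R <- 2; n <- 96
  g <- ring_pattern(R, n, 1)
  th <- uniform_theta_grid(12)
  kl <- seq(0.2, 1.0, by = 0.1)    # ring at 1/R = 0.5
  rg <- rabs_fourier(g, kl, kl, th, M = 128)
  pk <- arrayInd(which.max(abs(rg$values)), dim(rg$values))
  expect_equal(kl[pk[1]], 0.5)
  expect_equal(kl[pk[2]], 0.5)
  expect_equal(abs(th[pk[3]]), 2 * pi / 3, tolerance = 1e-9)
  # off-peak cells (excluding the two mirror peaks' neighbourhoods and the
  # degenerate collinear cells theta = pi, where the third wavevector has
  # length ~0 and B degenerates to |F|^2 F(0)) stay below 10% of the peak
  vals <- abs(rg$values)
  peak <- vals[pk]
  keep <- array(TRUE, dim(vals))
  for (i in seq_along(kl)) for (j in seq_along(kl)) for (c0 in seq_along(th)) {
    near_peak <- abs(kl[i] - 0.5) <= 0.11 && abs(kl[j] - 0.5) <= 0.11 &&
      min(abs(th[c0] - 2 * pi / 3), abs(th[c0] + 2 * pi / 3)) <= 0.61
    collinear <- abs(abs(th[c0]) - pi) <= 1e-9
    if (near_peak || collinear) keep[i, j, c0] <- FALSE
  }
  expect_lt(max(vals[keep]), 0.1 * peak)
})

test_that("RABS is motion invariant to machine precision on compact signals", {
  p <- random_pattern(4, R = 0.8, half = 2.5, seed = 41)
  g <- rasterize(p, 64, 0.5)
  th <- uniform_theta_grid(8)
  kl <- seq(0.3, 1.5, by = 0.3)
  r1 <- rabs_fourier(g, kl, kl, th, M = 64)
  g2 <- translate_signal(rotate90_signal(g), c(3, -5))
  r2 <- rabs_fourier(g2, kl, kl, th, M = 64)
  expect_lt(max(abs(r1$values - r2$values)) / max(abs(r1$values)), 1e-6)
  expect_lt(r1$meta$max_imag / max(abs(r1$values)), 1e-8)
})

test_that("harmonic patterns have vanishing RABS relative to the ring peak", {
  R <- 2; n <- 96
  th <- uniform_theta_grid(12)
  kl <- seq(0.2, 1.0, by = 0.1)
  ring_peak <- max(abs(rabs_fourier(ring_pattern(R, n, 1),
                                    kl, kl, th, M = 128)$values))
  for (m in c(1, 2, 10)) {
    gh <- harmonic_pattern(m, R, n, 1)
    rh <- rabs_fourier(gh, kl, kl, th, M = 128)
    expect_lt(max(abs(rh$values)), 1e-3 * ring_peak)
  }
})

test_that("mirror_map is an involution that tracks image mirroring", {
  p <- random_pattern(4, R = 0.8, half = 2.5, seed = 51)
  g <- rasterize(p, 65, 0.5)            # odd grid: mirroring is exact
  th <- uniform_theta_grid(8)
  kl <- seq(0.3, 1.2, by = 0.3)
  rg <- rabs_fourier(g, kl, kl, th, M = 64)
  rgm <- rabs_fourier(mirror_signal(g, 2), kl, kl, th, M = 64)
  expect_lt(max(abs(mirror_map(rgm)$values - rg$values)) /
              max(abs(rg$values)), 1e-6)
  expect_equal(mirror_map(mirror_map(rg))$values, rg$values)
  # achiral input: mirroring the invariant changes nothing
  ring <- rabs_fourier(ring_pattern(2, 64, 1), c(0.4, 0.5), c(0.4, 0.5),
                       th, M = 64)
  expect_lt(max(abs(mirror_map(ring)$values - ring$values)) /
              max(abs(ring$values)), 1e-6)
  bad <- rabs_grid(1, 1, c(0.3, 1.0), array(0, c(1, 1, 2)), space = "real")
  expect_error(mirror_map(bad), "symmetric")
})

test_that("real-route rabs transforms to the Fourier-route RABS", {
  p <- point_pattern(rbind(c(-0.9, 0.2), c(0.8, 0.6), c(0.1, -0.9)), R = 0.5)
  g <- rasterize(p, 48, 0.25)
  th <- uniform_theta_grid(24)
  rl <- seq(0.05, 5.3, by = 0.15)
  rr <- rabs_real(g, rl, rl, th, M = 48)
  kq <- c(0.5, 1.0, 1.5)
  tho <- uniform_theta_grid(8)
  RT <- rabs_real_to_fourier(rr, kq, kq, tho)
  RF <- rabs_fourier(g, kq, kq, tho, M = 128)
  expect_rel_equal(RT$values, RF$values, 0.05)
  # the transform commutes with the mirror map
  RTm <- rabs_real_to_fourier(mirror_map(rr), kq, kq, tho)
  expect_rel_equal(RTm$values, mirror_map(RT)$values, 1e-10,
                   scale = max(abs(RT$values)))
  # zero in, zero out
  z <- rabs_grid(rl, rl, th, array(0, c(length(rl), length(rl), length(th))),
                 space = "real")
  expect_true(all(rabs_real_to_fourier(z, kq, kq, tho)$values == 0))
  # a non-decayed boundary is reported
  nd <- rabs_grid(rl, rl, th, array(1, c(length(rl), length(rl), length(th))),
                  space = "real")
  expect_warning(rabs_real_to_fourier(nd, kq, kq, tho), "decayed")
})

test_that("punctate 3-point pattern concentrates rabs near its triangle", {
  # triangle with sides 2, ~2.24, ~3.16: probe pair (r, s) = two sides from
  # one vertex resonates
  p <- point_pattern(rbind(c(-1, 0), c(1, 0), c(0, 2)), R = 0.15)
  g <- rasterize(p, 64, 0.25)
  th <- uniform_theta_grid(16)
  rl <- seq(0.5, 3.5, by = 0.5)
  rg <- rabs_real(g, rl, rl, th, M = 64)
  pk <- arrayInd(which.max(rg$values), dim(rg$values))
  # the peak corresponds to a realizable (r, s, included-angle) triple of
  # the pattern: check its (r, s) are both pattern side lengths
  sides <- sort(pair_distances(p))
  expect_lt(min(abs(rl[pk[1]] - sides)), 0.5)
  expect_lt(min(abs(rl[pk[2]] - sides)), 0.5)
})
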