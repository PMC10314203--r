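test_that("triangle coordinates reproduce the hand-built construction", {
  # shortest side joins (0,0) and (0,1); opposite vertex (2,0);
  # unscaled drop = centroid - (2,0) = (-4/3, 1/3); short side oriented
  # toward (0,1), whose remaining leg (sqrt 5) is the longest
  tc <- triangle_coordinates(c(0, 0), c(2, 0), c(0, 1))
  expect_equal(tc$drop, 3^(3 / 4) / sqrt(2) * sqrt(16 / 9 + 1 / 9))
  expect_equal(tc$short, 3^(1 / 4) / sqrt(2))
  expect_equal(tc$theta, atan2(4, 1))
  expect_false(tc$degenerate)

  # brute-force confirmation over all vertex orderings
  P <- rbind(c(0, 0), c(2, 0), c(0, 1))
  for (pm in list(c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))) {
    tc2 <- triangle_coordinates(P[pm[1], ], P[pm[2], ], P[pm[3], ])
    expect_equal(c(tc2$drop, tc2$short, tc2$theta),
                 c(tc$drop, tc$short, tc$theta))
  }

  # equilateral: theta canonicalised to +pi/2, symmetric point drop = short
  te <- triangle_coordinates(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(te$theta, pi / 2)
  expect_equal(te$short / te$drop, 1, tolerance = 1e-9)
  expect_true(te$tie)

  # collinear and coincident degeneracies
  tl <- triangle_coordinates(c(0, 0), c(1, 0), c(3, 0))
  expect_true(tl$degenerate)
  expect_equal(tl$theta, 0)
  t0 <- triangle_coordinates(c(1, 1), c(1, 1), c(1, 1))
  expect_true(t0$degenerate)
  expect_equal(c(t0$drop, t0$short), c(0, 0))
  expect_error(triangle_coordinates(c(0, 0), c(1, NA), c(0, 1)), "finite")
})

test_that("triangle coordinates are motion invariant with mirror sign flip", {
  set.seed(61)
  for (i in 1:300) {
    P <- matrix(rnorm(6), 3, 2)
    tc <- triangle_coordinates(P[1, ], P[2, ], P[3, ])
    expect_lte(abs(tc$theta), pi / 2 + 1e-12)
    # random rotation + translation
    a <- runif(1, 0, 2 * pi)
    Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    Q <- t(Rm %*% t(P)) + rep(1, 3) %o% rnorm(2)
    tq <- triangle_coordinates(Q[1, ], Q[2, ], Q[3, ])
    expect_equal(c(tq$drop, tq$short, tq$theta),
                 c(tc$drop, tc$short, tc$theta), tolerance = 1e-8)
    # vertex permutation
    pm <- sample(3)
    tp <- triangle_coordinates(P[pm[1], ], P[pm[2], ], P[pm[3], ])
    expect_equal(c(tp$drop, tp$short, tp$theta),
                 c(tc$drop, tc$short, tc$theta), tolerance = 1e-9)
    # reflection
    M <- P; M[, 2] <- -M[, 2]
    tm <- triangle_coordinates(M[1, ], M[2, ], M[3, ])
    expect_equal(c(tm$drop, tm$short, -tm$theta),
                 c(tc$drop, tc$short, tc$theta), tolerance = 1e-8)
  }
})

test_that("enumerate_triangles counts C(N,3) and mirrors theta-wise", {
  p5 <- random_pattern(5, R = 0.1, seed = 71)
  tab <- enumerate_triangles(p5)
  expect_equal(nrow(tab), 10L)
  expect_equal(nrow(enumerate_triangles(random_pattern(3, 0.1, seed = 1))), 1L)
  expect_equal(nrow(enumerate_triangles(random_pattern(6, 0.1, seed = 1))), 20L)
  expect_error(enumerate_triangles(random_pattern(2, 0.1, seed = 1)), "at least 3")

  # mirrored pattern: same (drop, short), negated theta, identical distances
  mtab <- enumerate_triangles(mirror_pattern(p5, 2))
  expect_equal(mtab$drop, tab$drop, tolerance = 1e-10)
  expect_equal(mtab$short, tab$short, tolerance = 1e-10)
  expect_equal(mtab$theta, -tab$theta, tolerance = 1e-10)
  expect_equal(sort(pair_distances(mirror_pattern(p5, 2))),
               sort(pair_distances(p5)))
})

test_that("every random triangle lies in the asymmetric unit", {
  bound <- asymmetric_unit_bound(n_theta = 45, n_grid = 150)
  # equilateral sits on the boundary: extremal ratio 1 at |theta| = pi/2
  expect_equal(max(bound$max_ratio), 1, tolerance = 0.02)
  expect_equal(bound$max_ratio[nrow(bound)], 1, tolerance = 0.02)
  set.seed(81)
  n_bad <- 0L
  for (i in 1:2000) {
    P <- matrix(rnorm(6), 3, 2)
    tc <- triangle_coordinates(P[1, ], P[2, ], P[3, ])
    if (!asymmetric_unit_check(tc, bound)) n_bad <- n_bad + 1L
  }
  expect_equal(n_bad, 0L)
  # collinear: interior at theta = 0
  tl <- triangle_coordinates(c(0, 0), c(1, 0), c(3, 0))
  chk <- asymmetric_unit_check(tl, bound)
  expect_true(chk)
  expect_lt(attr(chk, "ratio"), attr(chk, "ratio_bound"))
})

test_that("closed-form rabs peaks at the pattern's own triangle coordinates", {
  set.seed(91)
  # R must be small against the spacing of the pattern's triangle
  # coordinates: each bump has width 3^(1/4) R, and neighbouring bumps
  # merge (shifting local maxima) once widths approach that spacing
  p <- point_pattern(matrix(runif(10, -1.5, 1.5), 5, 2), R = 0.02)
  tab <- enumerate_triangles(p)
  step <- 0.05
  for (i in seq_len(nrow(tab))) {
    # the local maximum reached from the triangle's coordinates lies within
    # half a grid step of them
    # cross terms only: the repeated-index self terms form an
    # arrangement-blind ridge along w = 0 (see ?rabs_closed_form)
    opt <- stats::optim(c(tab$drop[i], tab$short[i], tab$theta[i]),
                        function(x) -rabs_closed_form(p, x[1], x[2], x[3],
                                                      cross_only = TRUE),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-10,
                                       parscale = rep(0.2, 3)))
    expect_lte(abs(opt$par[1] - tab$drop[i]), step / 2)
    expect_lte(abs(opt$par[2] - tab$short[i]), step / 2)
    expect_lte(abs(opt$par[3] - tab$theta[i]), step / 2)
  }
  # mirrored pattern gives the theta-negated landscape pointwise
  v <- runif(40, 0.5, 2); w <- runif(40, 0.3, 1.5); t <- runif(40, -1.5, 1.5)
  expect_equal(rabs_closed_form(mirror_pattern(p, 2), v, w, t),
               rabs_closed_form(p, v, w, -t), tolerance = 1e-8)
})

test_that("closed-form rabs agrees with the rasterised grid oracle", {
  set.seed(92)
  p <- point_pattern(matrix(runif(6, -1, 1), 3, 2), R = 0.4)
  g <- rasterize(p, 48, 0.25)
  shapes <- rbind(c(1.0, 1.2, 0.9), c(0.8, 1.5, -1.7),
                  c(1.8, 0.6, 2.5), c(1.2, 1.2, -0.5))
  peak_scale <- max(rabs_closed_form(p, shapes[, 1], shapes[, 2], shapes[, 3]))
  for (i in seq_len(nrow(shapes))) {
    r <- shapes[i, 1]; s <- shapes[i, 2]; tsr <- shapes[i, 3]
    rg <- rabs_real(g, r, s, theta = c(tsr, pi), M = 256)
    tc <- triangle_coordinates(c(0, 0), c(r, 0),
                               s * c(cos(tsr), sin(tsr)))
    cf <- rabs_closed_form(p, tc$drop, tc$short, tc$theta)
    expect_lt(abs(rg$values[1, 1, 1] - cf) / peak_scale, 0.05)
  }
})

test_that("closed-form rabs conserves total three-point mass", {
  # integral with the r s measure equals N^3 (the triangle-coordinate map
  # is area preserving under the package scalings), independent of the
  # arrangement of the centers
  set.seed(93)
  tot <- function(pp) {
    vg <- seq(0.02, 7, by = 0.07); wg <- seq(0.02, 7, by = 0.07)
    tg <- uniform_theta_grid(36)
    g <- rabs_closed_form_grid(pp, vg, wg, tg)
    ww <- outer(vg, wg)
    s <- 0
    for (c0 in seq_along(tg)) s <- s + sum(ww * g$values[, , c0])
    2 * pi * s * 0.07 * 0.07 * (2 * pi / 36)
  }
  t1 <- tot(point_pattern(matrix(runif(6, -1, 1), 3, 2), R = 0.15))
  t2 <- tot(point_pattern(matrix(runif(6, -1.2, 1.2), 3, 2), R = 0.15))
  expect_equal(t1, 27, tolerance = 0.02)
  expect_equal(t2, 27, tolerance = 0.02)
})
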