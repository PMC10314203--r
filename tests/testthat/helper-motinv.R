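# Shared fixtures and independent oracles, all generated in code.

# random point pattern inside a centred box
random_pattern <- function(n, R, half = 1, dim = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  point_pattern(matrix(stats::runif(n * dim, -half, half), n, dim), R = R)
}

# direct O(n^2 * n^2) periodic autocorrelation oracle for a small 2D grid
brute_autocorr <- function(v, spacing = 1) {
  n <- nrow(v)
  out <- matrix(0, n, n)
  for (ti in 0:(n - 1)) for (tj in 0:(n - 1)) {
    acc <- 0
    for (i in 1:n) for (j in 1:n) {
      acc <- acc + v[i, j] * v[(i - 1 + ti) %% n + 1, (j - 1 + tj) %% n + 1]
    }
    out[ti + 1, tj + 1] <- acc
  }
  out * spacing^2
}

# direct triple-sum three-point function oracle at integer offsets r, s
brute_b <- function(v, r, s, spacing = 1) {
  n <- nrow(v)
  acc <- 0
  for (i in 1:n) for (j in 1:n) {
    acc <- acc + v[i, j] *
      v[(i - 1 + r[1]) %% n + 1, (j - 1 + r[2]) %% n + 1] *
      v[(i - 1 + s[1]) %% n + 1, (j - 1 + s[2]) %% n + 1]
  }
  acc * spacing^2
}

# rotate an integer 2-vector by k quarter turns
rot90_vec <- function(v, k) {
  for (i in seq_len(k %% 4)) v <- c(-v[2], v[1])
  v
}

expect_rel_equal <- function(actual, expected, tol, scale = max(abs(expected))) {
  expect_lt(max(abs(actual - expected)) / scale, tol)
}
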