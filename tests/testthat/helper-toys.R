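# Shared fixtures: random PSD covariances, a linear-Gaussian toy system and
# its exact Kalman recursion (the analytic oracle the sigma-point filters
# must reproduce on linear dynamics).

random_psd <- function(n, scale = 1) {
  A <- matrix(rnorm(n * n), n, n)
  scale * (crossprod(A) / n + diag(n) * 0.1)
}

# Planar rotation with per-axis damping: the exact discrete flow of a
# linear ODE, used as a linear point propagator.
rotation_F <- function(dt = 1, damp = 0.98) {
  damp * matrix(c(cos(dt), -sin(dt), sin(dt), cos(dt)), 2, 2)
}

linear_propagator <- function(F) function(pts, t, dt) F %*% pts

# Textbook linear Kalman filter (prediction + scalar update), the oracle.
kalman_oracle <- function(y, m0, P0, F, Q, H, R) {
  n <- length(m0)
  means <- matrix(NA_real_, length(y), n)
  m <- m0; P <- P0
  for (k in seq_along(y)) {
    m <- drop(F %*% m)
    P <- F %*% P %*% t(F) + Q
    S <- drop(H %*% P %*% t(H)) + R
    K <- P %*% t(H) / S
    m <- m + drop(K) * (y[k] - drop(H %*% m))
    P <- (diag(n) - K %*% H) %*% P
    means[k, ] <- m
  }
  means
}

# Simulate the linear-Gaussian toy truth + measurements.
simulate_linear_toy <- function(N, F, Q, H, R, x0, seed = 1) {
  set.seed(seed)
  n <- length(x0)
  Lq <- t(chol(Q))
  x <- x0
  xs <- matrix(NA_real_, N, n)
  y <- numeric(N)
  for (k in seq_len(N)) {
    x <- drop(F %*% x) + drop(Lq %*% rnorm(n))
    xs[k, ] <- x
    y[k] <- drop(H %*% x) + rnorm(1, sd = sqrt(R))
  }
  list(states = xs, y = y)
}

# Small study configuration used where full 24 h runs are unnecessary.
quick_config <- function(...) {
  args <- modifyList(list(horizon = 120, mc_runs = 2, seed = 42,
                          meals = meal_schedule(10000, 30, 1000)),
                     list(...))
  do.call(experiment_config, args)
}
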