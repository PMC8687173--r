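test_that("filter_spec validates its pieces", {
  expect_error(filter_spec("ukf", Q = diag(c(1, -1, rep(1, 10)), 12), R = 16),
               "semi-definite")
  expect_error(filter_spec("ukf", Q = diag(12), R = 0), "positive")
  expect_error(filter_spec("ukf", Q = diag(3), R = 1), "12-dimensional")
  s <- filter_spec("ukf", Q = rep(0.1, 12), R = 16)
  expect_equal(s$kappa, 3 - 12)
  expect_equal(which(s$H != 0), 4L)  # measures plasma glucose mass
})

test_that("time update is exact in the Dirac (zero-covariance) limit", {
  p <- cohort_parameters("normal")
  sch <- standard_meal_schedule()
  x <- table_initial_state(p)
  for (flav in c("ukf", "cqkf")) {
    spec <- filter_spec(flav, Q = diag(0, 12), R = 16, dt = 1)
    b <- gaussian_belief(x, diag(0, 12))
    pred <- time_update(b, spec, sch, p, t = 0)
    flow <- glucofilt:::rk4_propagate(matrix(x, ncol = 1), 0, 1, 0.1,
                                      glucofilt:::meal_matrix(sch),
                                      glucofilt:::par_vector(p))
    expect_equal(pred$mean, as.numeric(flow), tolerance = 1e-6)
    expect_lt(max(abs(pred$cov)), 1e-6)
  }
})

test_that("time update matches the exact linear-Gaussian prediction", {
  F <- rotation_F(dt = 1)
  Q <- diag(c(0.3, 0.2))
  m <- c(1, -2)
  P <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  exact_m <- drop(F %*% m)
  exact_P <- F %*% P %*% t(F) + Q
  for (flav in c("ukf", "cqkf")) {
    spec <- filter_spec(flav, Q = Q, R = 1, H = matrix(c(1, 0), 1),
                        propagate = linear_propagator(F))
    pred <- time_update(gaussian_belief(m, P), spec)
    expect_equal(pred$mean, exact_m, tolerance = 1e-8)
    expect_equal(pred$cov, exact_P, tolerance = 1e-8)
    # additive noise: predicted covariance dominates Q
    ev <- eigen(pred$cov - Q, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-9)
  }
})

test_that("measurement update reproduces hand Kalman algebra", {
  # scalar system: P = 4, R = 16, H = 1, prior mean 0, y = 5
  spec <- filter_spec("ukf", Q = matrix(1), R = 16, H = matrix(1),
                      propagate = linear_propagator(matrix(1)))
  post <- measurement_update(gaussian_belief(0, matrix(4)), 5, spec)
  expect_equal(post$mean, 1.0)
  expect_equal(drop(post$cov), 3.2)
  expect_equal(attr(post, "innovation"), 5)
  expect_equal(attr(post, "innovation_variance"), 20)

  # uninformative measurement: posterior = prior
  spec_inf <- filter_spec("ukf", Q = matrix(1), R = 1e12, H = matrix(1),
                          propagate = linear_propagator(matrix(1)))
  post <- measurement_update(gaussian_belief(3, matrix(4)), 100, spec_inf)
  expect_equal(post$mean, 3, tolerance = 1e-9)
  expect_equal(drop(post$cov), 4, tolerance = 1e-9)

  # perfect prior: measurement cannot move it
  post <- measurement_update(gaussian_belief(3, matrix(0)), 100, spec)
  expect_equal(post$mean, 3)
  expect_equal(drop(post$cov), 0)

  expect_error(measurement_update(gaussian_belief(0, matrix(4)), NaN, spec),
               "finite")
})

test_that("measurement update never inflates the covariance trace", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(c(2, 6, 12), 1)
    P <- random_psd(n, scale = runif(1, 0.1, 100))
    H <- matrix(0, 1, n); H[1, sample(n, 1)] <- 1
    spec <- filter_spec("ukf", Q = diag(n), R = runif(1, 0.1, 50), H = H,
                        propagate = linear_propagator(diag(n)))
    post <- measurement_update(gaussian_belief(rnorm(n), P), rnorm(1, sd = 5),
                               spec)
    expect_lte(sum(diag(post$cov)), sum(diag(P)) + 1e-8)
  }
})

test_that("both filters reproduce the analytic Kalman filter on a linear system", {
  F <- rotation_F(dt = 1)
  Q <- diag(c(0.2, 0.3))
  H <- matrix(c(1, 0), 1)
  R <- 0.5
  m0 <- c(0, 0)
  P0 <- diag(2)
  toy <- simulate_linear_toy(80, F, Q, H, R, c(1, 1), seed = 5)
  oracle <- kalman_oracle(toy$y, m0, P0, F, Q, H, R)
  for (flav in c("ukf", "cqkf")) {
    spec <- filter_spec(flav, Q = Q, R = R, H = H,
                        propagate = linear_propagator(F))
    fit <- run_filter(toy$y, gaussian_belief(m0, P0), spec)
    expect_lt(max(abs(fit$mean - oracle)), 1e-8)
  }
  # and therefore the two filters coincide with each other
  s1 <- filter_spec("ukf", Q = Q, R = R, H = H, propagate = linear_propagator(F))
  s2 <- filter_spec("cqkf", Q = Q, R = R, H = H, propagate = linear_propagator(F))
  f1 <- run_filter(toy$y, gaussian_belief(m0, P0), s1)
  f2 <- run_filter(toy$y, gaussian_belief(m0, P0), s2)
  expect_lt(max(abs(f1$mean - f2$mean)), 1e-8)
})

test_that("noise-free, exactly initialized filters track the model truth", {
  p <- cohort_parameters("normal")
  sch <- standard_meal_schedule()
  x0 <- table_initial_state(p)
  truth <- simulate_model(x0, sch, p, horizon = 1440, step = 1)
  y <- truth$Gp[-1]  # exact plasma-glucose measurements
  for (flav in c("ukf", "cqkf")) {
    spec <- filter_spec(flav, Q = diag(0, 12), R = 1e-8, dt = 1)
    fit <- run_filter(y, gaussian_belief(x0, diag(0, 12)), spec, sch, p)
    expect_lt(max(abs(fit$mean[, "Gp"] - y)), 1e-3)
  }
})

test_that("prediction-only steps bridge measurement gaps", {
  p <- cohort_parameters("normal")
  sch <- meal_schedule()
  x0 <- basal_state(p)
  spec <- filter_spec("ukf", Q = rep(0.1, 12), R = 16, dt = 1)
  y <- rep(x0[["Gp"]], 30)
  y[10:15] <- NA
  fit <- run_filter(y, gaussian_belief(x0, diag(0.1, 12)), spec, sch, p)
  expect_true(all(is.na(fit$innovation[10:15])))
  expect_true(all(!is.na(fit$mean)))
  # uncertainty grows while no measurement arrives
  expect_gt(fit$sd[15, "Gp"], fit$sd[9, "Gp"])
})

test_that("filter failures report the step index", {
  spec <- filter_spec("ukf", Q = matrix(1), R = 1, H = matrix(1),
                      propagate = function(pts, t, dt) pts * NaN)
  expect_error(
    run_filter(c(1, 2), gaussian_belief(0, matrix(1)), spec),
    "step 1")
})
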