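#' Experiment configuration
#'
#' The full specification of one estimation study: cohort, meal schedule,
#' horizon, sampling, noise covariances, filter initialization and
#' Monte-Carlo settings. Defaults reproduce the benchmark study: 24 h at
#' 1-min sampling, three meals (37/74/74 g at 3.7 g/min), process noise
#' `Q = diag(1, 0.1 x 11)`, measurement noise `R = 16` (mg/kg)^2 on
#' plasma glucose mass, initial covariance
#' `P0 = diag(400^2, 0.1, 0.1, 0.1, 200^2, 0.3, 100, 10, 10, 30, 0.1, 0.5)`,
#' tabulated initial means, 50 Monte-Carlo runs.
#'
#' @param cohort `"normal"` or `"t2dm"`.
#' @param meals a [meal_schedule()].
#' @param horizon study length (min).
#' @param dt sampling interval (min).
#' @param Q process-noise covariance (length-12 diagonal or 12 x 12).
#' @param R measurement-noise variance (scalar).
#' @param P0 initial error covariance (length-12 diagonal or 12 x 12).
#' @param init_mean filter/truth initial mean (default
#'   [table_initial_state()] of the cohort).
#' @param mc_runs number of Monte-Carlo trials.
#' @param seed base random seed; trial `j` uses `seed + j`.
#' @param flavours filter flavours to run.
#' @param kappa,nprime point-set parameters (see [filter_spec()]).
#' @param burnin_min burn-in window excluded from summary statistics.
#' @param noisy_truth if `TRUE` (default) the truth integrates the model
#'   plus per-step additive process noise `N(0, Q)`; if `FALSE` the truth
#'   is deterministic.
#' @param random_init if `TRUE` (default) each trial draws the filter's
#'   initial mean from `N(init_mean, P0)` (mass states clipped at 0);
#'   if `FALSE` the filter starts exactly at `init_mean`.
#' @param params optional [cohort_parameters()] override; default is the
#'   cohort's built-in profile.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = c("normal", "t2dm"),
                              meals = standard_meal_schedule(),
                              horizon = 1440, dt = 1,
                              Q = c(1, rep(0.1, 11)), R = 16,
                              P0 = c(400^2, 0.1, 0.1, 0.1, 200^2, 0.3,
                                     100, 10, 10, 30, 0.1, 0.5),
                              init_mean = NULL,
                              mc_runs = 50, seed = 1,
                              flavours = c("ukf", "cqkf"),
                              kappa = 3 - 12, nprime = 2,
                              burnin_min = 60,
                              noisy_truth = TRUE, random_init = TRUE,
                              params = NULL) {
  cohort <- match.arg(cohort)
  if (is.null(params)) params <- cohort_parameters(cohort)
  if (is.vector(Q)) {
    if (length(Q) != 12L) stop("diagonal Q must have 12 entries")
    Q <- diag(Q, 12)
  }
  if (is.vector(P0)) {
    if (length(P0) != 12L) stop("diagonal P0 must have 12 entries")
    P0 <- diag(P0, 12)
  }
  if (is.null(init_mean)) init_mean <- table_initial_state(params)
  if (length(init_mean) != 12L) stop("init_mean must have 12 entries")
  flavours <- match.arg(flavours, c("ukf", "cqkf"), several.ok = TRUE)
  if (mc_runs < 1) stop("mc_runs must be at least 1")
  if (horizon <= 0 || dt <= 0 || abs(horizon / dt - round(horizon / dt)) > 1e-9)
    stop("dt must divide horizon")
  structure(list(cohort = cohort, meals = meals, horizon = horizon, dt = dt,
                 Q = as.matrix(Q), R = R, P0 = as.matrix(P0),
                 init_mean = setNames(as.numeric(init_mean), STATE_NAMES),
                 mc_runs = as.integer(mc_runs), seed = as.integer(seed),
                 flavours = flavours, kappa = kappa,
                 nprime = as.integer(nprime), burnin_min = burnin_min,
                 noisy_truth = isTRUE(noisy_truth),
                 random_init = isTRUE(random_init), params = params),
            class = "experiment_config")
}

# Independent sub-stream seeds for one trial (all well below 2^31).
trial_seeds <- function(base_seed, j) {
  s <- (base_seed + j) %% 715827881L  # keep 3*s + 2 < 2^31
  list(process = 3L * s, measurement = 3L * s + 1L, init = 3L * s + 2L)
}

#' Generate a (possibly noisy) truth trajectory
#'
#' Per sampling step: deterministic RK4 flow of the model, then an
#' additive draw from `N(0, Q)`, then clipping of the nonnegative states
#' at zero. With `config$noisy_truth = FALSE` (or `Q = 0`) this
#' coincides with [simulate_model()]'s state trajectory.
#'
#' @param config an [experiment_config()].
#' @param seed integer seed for the process-noise stream.
#' @return An object of class `truth_trajectory`: `t_min` (length
#'   steps + 1, starting at 0), `states` ((steps + 1) x 12), the
#'   `seed`, the generating `config`, and `shocks` — the raw 12 x steps
#'   matrix of noise draws actually added (before clipping; `NULL` for a
#'   deterministic truth), kept for noise-calibration diagnostics.
#' @export
generate_truth <- function(config, seed = config$seed) {
  nsteps <- as.integer(round(config$horizon / config$dt))
  states <- matrix(NA_real_, nsteps + 1L, 12,
                   dimnames = list(NULL, STATE_NAMES))
  x <- matrix(config$init_mean, ncol = 1)
  states[1L, ] <- x
  mm <- meal_matrix(config$meals)
  pv <- par_vector(config$params)
  noisy <- config$noisy_truth && any(config$Q != 0)
  shocks <- NULL
  if (noisy) {
    Lq <- sqrt_psd(config$Q)
    set.seed(seed)
    shocks <- Lq %*% matrix(rnorm(12L * nsteps), 12L, nsteps)
  }
  for (k in seq_len(nsteps)) {
    x <- rk4_propagate(x, (k - 1) * config$dt, config$dt, 0.1, mm, pv)
    if (noisy) {
      x[, 1] <- x[, 1] + shocks[, k]
      x[NONNEG_STATES, 1] <- pmax(x[NONNEG_STATES, 1], 0)
    }
    states[k + 1L, ] <- x
  }
  structure(list(t_min = seq(0, config$horizon, by = config$dt),
                 states = states, seed = seed, config = config,
                 shocks = shocks),
            class = "truth_trajectory")
}

#' Synthesize plasma-glucose measurements from a truth trajectory
#'
#' `y_k = Gp_k + v_k` with `v_k ~ N(0, R)` i.i.d., drawn from a
#' measurement-noise stream independent of the process noise. One
#' measurement per sampling step (the initial state is not measured).
#'
#' @param truth a [generate_truth()] result.
#' @param R measurement-noise variance.
#' @param seed integer seed for the measurement-noise stream.
#' @return Numeric measurement series of length `steps`.
#' @export
generate_measurements <- function(truth, R = truth$config$R,
                                  seed = truth$config$seed + 1L) {
  if (R < 0) stop("R must be nonnegative")
  gp <- truth$states[-1L, "Gp"]
  set.seed(seed)
  gp + rnorm(length(gp), sd = sqrt(R))
}

#' Run one estimation trial
#'
#' Generates truth and measurements from the trial's seed sub-streams,
#' initializes the filter belief (tabulated means, `P0`; the mean drawn
#' from `N(init_mean, P0)` unless `config$random_init = FALSE`), runs the
#' requested filter, and records per-state squared estimation errors.
#'
#' @param config an [experiment_config()].
#' @param flavour `"ukf"` or `"cqkf"`.
#' @param j trial index (used for the seed sub-streams; the truth and
#'   measurements for a given `j` are identical across flavours).
#' @param keep_cov passed to [run_filter()].
#' @return List with `truth`, `measurements`, `fit` (a `filter_result`),
#'   `sq_err` (steps x 12) and `elapsed` (seconds).
#' @export
run_single_trial <- function(config, flavour = config$flavours[1], j = 1L,
                             keep_cov = FALSE) {
  seeds <- trial_seeds(config$seed, j)
  truth <- generate_truth(config, seed = seeds$process)
  y <- generate_measurements(truth, config$R, seed = seeds$measurement)
  m0 <- config$init_mean
  if (config$random_init) {
    set.seed(seeds$init)
    m0 <- m0 + drop(sqrt_psd(config$P0) %*% rnorm(12))
    m0[NONNEG_STATES] <- pmax(m0[NONNEG_STATES], 0)
  }
  spec <- filter_spec(flavour, Q = config$Q, R = config$R,
                      kappa = config$kappa, nprime = config$nprime,
                      dt = config$dt)
  belief0 <- gaussian_belief(m0, config$P0)
  elapsed <- system.time(
    fit <- run_filter(y, belief0, spec, config$meals, config$params,
                      keep_cov = keep_cov)
  )[["elapsed"]]
  sq_err <- (truth$states[-1L, , drop = FALSE] - fit$mean)^2
  list(truth = truth, measurements = y, fit = fit, sq_err = sq_err,
       elapsed = elapsed)
}

#' Monte-Carlo RMSE of a filter
#'
#' Runs `config$mc_runs` independent trials (trial `j` seeded with
#' `seed + j`) and computes, per state and per time step, the root mean
#' square estimation error across trials:
#' `RMSE_k = sqrt(mean_j (x_{j,k} - xhat_{j,k})^2)`.
#'
#' @param config an [experiment_config()].
#' @param flavour `"ukf"` or `"cqkf"`.
#' @return An object of class `rmse_series`: data frame `t_min` + one
#'   RMSE column per state, with attributes `flavour`, `mc_runs`,
#'   `elapsed` (total filter seconds) and `post_burnin` (named vector of
#'   time-averaged RMSE after `config$burnin_min`).
#' @export
monte_carlo_rmse <- function(config, flavour = config$flavours[1]) {
  acc <- NULL
  total_elapsed <- 0
  for (j in seq_len(config$mc_runs)) {
    trial <- tryCatch(run_single_trial(config, flavour, j),
                      error = function(e)
                        stop("trial ", j, " (seed ", config$seed + j,
                             ") failed: ", conditionMessage(e), call. = FALSE))
    acc <- if (is.null(acc)) trial$sq_err else acc + trial$sq_err
    total_elapsed <- total_elapsed + trial$elapsed
  }
  rmse <- sqrt(acc / config$mc_runs)
  t_min <- seq_len(nrow(rmse)) * config$dt
  out <- data.frame(t_min = t_min)
  out <- cbind(out, as.data.frame(rmse))
  keep <- t_min > config$burnin_min
  if (!any(keep)) keep <- rep(TRUE, length(t_min))  # horizon within burn-in
  post <- colMeans(rmse[keep, , drop = FALSE])
  structure(out, class = c("rmse_series", "data.frame"),
            flavour = flavour, mc_runs = config$mc_runs,
            elapsed = total_elapsed, post_burnin = post)
}

#' Compare the UKF and the CQKF on one configuration
#'
#' Runs the Monte-Carlo RMSE study for both filter flavours on identical
#' truth/measurement realizations and reports per-state RMSE series,
#' time-averaged post-burn-in RMSE and the measured relative wall-clock
#' ratio (CQKF time / UKF time; informational, hardware-dependent).
#'
#' @param config an [experiment_config()] with both flavours enabled.
#' @return An object of class `filter_comparison`: list with `ukf` and
#'   `cqkf` ([monte_carlo_rmse()] results), `post_burnin` (2 x 12
#'   matrix) and `wallclock_ratio`.
#' @export
compare_filters <- function(config) {
  if (!all(c("ukf", "cqkf") %in% config$flavours))
    stop("both filter flavours must be enabled in the configuration")
  r_ukf <- monte_carlo_rmse(config, "ukf")
  r_cqkf <- monte_carlo_rmse(config, "cqkf")
  post <- rbind(ukf = attr(r_ukf, "post_burnin"),
                cqkf = attr(r_cqkf, "post_burnin"))
  structure(list(ukf = r_ukf, cqkf = r_cqkf, post_burnin = post,
                 wallclock_ratio = attr(r_cqkf, "elapsed") /
                   attr(r_ukf, "elapsed")),
            class = "filter_comparison")
}

#' @export
print.filter_comparison <- function(x, ...) {
  cat("Filter comparison over", attr(x$ukf, "mc_runs"), "Monte-Carlo runs\n")
  cat("Time-averaged post-burn-in RMSE per state:\n")
  print(round(x$post_burnin, 4))
  cat(sprintf("Relative wall-clock time (CQKF / UKF): %.2f\n",
              x$wallclock_ratio))
  invisible(x)
}
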