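#' Filter configuration
#'
#' Collects everything a sigma-point filter needs besides the model:
#' flavour, point-set parameters, noise covariances, the measurement
#' matrix and the sampling interval. The measurement model is linear,
#' `y_k = H x_k + v_k` with `v_k ~ N(0, R)`; by default `H` selects the
#' plasma glucose mass `Gp` (fourth state), so `y` and `R` are in
#' `Gp`'s units (mg/kg).
#'
#' @param flavour `"ukf"` or `"cqkf"`.
#' @param Q process-noise covariance (n x n matrix, or its diagonal as a
#'   vector; n = 12 for the glucose-insulin model).
#' @param R measurement-noise variance (scalar, > 0).
#' @param kappa unscented scaling parameter (default `3 - n`).
#' @param nprime radial quadrature order of the CQ rule (default 2).
#' @param H 1 x n measurement matrix (default for n = 12: selector of `Gp`).
#' @param dt sampling interval (min).
#' @param substep integrator substep used inside the time update (min).
#' @param propagate optional custom point propagator
#'   `function(points, t, dt) -> points`, substituted for the model
#'   dynamics (used to run the filters on test systems). `NULL` selects
#'   the glucose-insulin model.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(flavour = c("ukf", "cqkf"), Q, R,
                        kappa = NULL, nprime = 2,
                        H = NULL, dt = 1, substep = 0.1, propagate = NULL) {
  flavour <- match.arg(flavour)
  if (is.vector(Q)) Q <- diag(Q, length(Q))
  Q <- as.matrix(Q)
  n <- nrow(Q)
  if (ncol(Q) != n) stop("Q must be square (or a diagonal given as a vector)")
  if (is.null(propagate) && n != 12L)
    stop("the glucose-insulin model requires a 12-dimensional Q")
  ev <- eigen((Q + t(Q)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9 * max(abs(ev), 1)) stop("Q must be positive semi-definite")
  if (!is.numeric(R) || length(R) != 1L || R <= 0) stop("R must be a positive scalar")
  if (is.null(H)) {
    if (n != 12L) stop("H must be given explicitly for non-model systems")
    H <- matrix(0, 1, 12)
    H[1, 4] <- 1
  }
  H <- matrix(as.numeric(H), nrow = 1)
  if (ncol(H) != n) stop("H must be 1 x n")
  if (dt <= 0) stop("dt must be positive")
  if (is.null(kappa)) kappa <- 3 - n
  structure(list(flavour = flavour, Q = (Q + t(Q)) / 2, R = R,
                 kappa = kappa, nprime = as.integer(nprime), H = H, dt = dt,
                 substep = substep, propagate = propagate, n = n),
            class = "filter_spec")
}

belief_points <- function(belief, spec) {
  switch(spec$flavour,
         ukf = unscented_points(belief, spec$kappa),
         cqkf = cubature_quadrature_points(belief, spec$nprime))
}

#' Filter time update (prediction)
#'
#' Draws the spec's point set from the current belief, propagates every
#' point through the deterministic model dynamics over one sampling
#' interval, recombines the weighted moments and adds the discrete
#' process-noise covariance `Q`. The predicted covariance is symmetrized
#' and repaired to positive semi-definite if the (possibly negative)
#' point weights have pushed it slightly indefinite.
#'
#' @param belief a [gaussian_belief()] (dimension 12).
#' @param spec a [filter_spec()].
#' @param schedule a [meal_schedule()].
#' @param params a [cohort_parameters()] object.
#' @param t start time of the interval (min).
#' @return The predicted [gaussian_belief()].
#' @export
time_update <- function(belief, spec, schedule = NULL, params = NULL, t = 0) {
  ps <- belief_points(belief, spec)
  prop <- if (is.null(spec$propagate)) {
    rk4_propagate(ps$points, t, spec$dt, spec$substep,
                  meal_matrix(schedule), par_vector(params))
  } else {
    spec$propagate(ps$points, t, spec$dt)
  }
  if (any(!is.finite(prop)))
    stop("point propagation produced non-finite values")
  mom <- points_moments(list(points = prop, weights = ps$weights))
  new_belief(mom$mean, repair_psd(mom$cov + spec$Q))
}

#' Filter measurement update (correction)
#'
#' Exact linear Kalman update for the linear measurement model
#' `y = H x + v`: gain `K = P H' (H P H' + R)^-1`, mean shifted by the
#' gained innovation, covariance contracted to `(I - K H) P` and
#' symmetrized.
#'
#' @param pred the predicted [gaussian_belief()].
#' @param y scalar measurement.
#' @param spec a [filter_spec()].
#' @return The posterior [gaussian_belief()], with attributes
#'   `innovation` (y - H x_pred) and `innovation_variance`
#'   (`H P H' + R`).
#' @export
measurement_update <- function(pred, y, spec) {
  if (!is.finite(y)) stop("measurement must be finite")
  H <- spec$H
  P <- pred$cov
  Sv <- drop(H %*% P %*% t(H)) + spec$R
  if (Sv <= 0) stop("innovation variance is not positive")
  K <- P %*% t(H) / Sv
  innov <- y - drop(H %*% pred$mean)
  m <- pred$mean + drop(K) * innov
  Ppost <- (diag(nrow(P)) - K %*% H) %*% P
  post <- new_belief(m, repair_psd(Ppost))
  attr(post, "innovation") <- innov
  attr(post, "innovation_variance") <- Sv
  post
}

#' Run a sigma-point filter over a measurement series
#'
#' Alternates [time_update()] and [measurement_update()] starting from an
#' initial belief. Measurements are assumed aligned to the sampling grid
#' `t0 + dt, t0 + 2 dt, ...`; an `NA` measurement yields a
#' prediction-only step.
#'
#' @param y numeric measurement series (may contain `NA` gaps).
#' @param x0_belief initial [gaussian_belief()].
#' @param spec a [filter_spec()].
#' @param schedule a [meal_schedule()].
#' @param params a [cohort_parameters()] object.
#' @param t0 time of the initial belief (min).
#' @param keep_cov if `TRUE`, retain the full 12 x 12 posterior
#'   covariance at every step (array `cov`).
#' @return An object of class `filter_result`: `t_min`, `mean`
#'   (steps x 12), `sd` (steps x 12), `innovation`,
#'   `innovation_variance`, optionally `cov`, plus the `spec`.
#' @export
run_filter <- function(y, x0_belief, spec, schedule = NULL, params = NULL,
                       t0 = 0, keep_cov = FALSE) {
  N <- length(y)
  n <- spec$n
  snames <- if (n == 12L) STATE_NAMES else paste0("x", seq_len(n))
  mean_out <- matrix(NA_real_, N, n, dimnames = list(NULL, snames))
  sd_out <- matrix(NA_real_, N, n, dimnames = list(NULL, snames))
  innov <- rep(NA_real_, N)
  innov_var <- rep(NA_real_, N)
  covs <- if (keep_cov) array(NA_real_, c(n, n, N)) else NULL

  if (is.null(spec$propagate)) {
    # bind the model propagator once (avoids per-step conversion work)
    mm <- meal_matrix(schedule)
    pv <- par_vector(params)
    substep <- spec$substep
    spec$propagate <- function(pts, t, dt)
      rk4_propagate(pts, t, dt, substep, mm, pv)
  }

  belief <- x0_belief
  for (k in seq_len(N)) {
    t_k <- t0 + (k - 1) * spec$dt
    belief <- tryCatch({
      b <- time_update(belief, spec, schedule, params, t_k)
      if (!is.na(y[k])) b <- measurement_update(b, y[k], spec)
      b
    }, error = function(e) stop("filter failed at step ", k, ": ",
                                conditionMessage(e), call. = FALSE))
    if (!is.na(y[k])) {
      innov[k] <- attr(belief, "innovation")
      innov_var[k] <- attr(belief, "innovation_variance")
    }
    mean_out[k, ] <- belief$mean
    sd_out[k, ] <- sqrt(pmax(diag(belief$cov), 0))
    if (keep_cov) covs[, , k] <- belief$cov
  }
  structure(list(t_min = t0 + seq_len(N) * spec$dt, mean = mean_out,
                 sd = sd_out, innovation = innov,
                 innovation_variance = innov_var, cov = covs, spec = spec),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("%s filter result: %d steps, %d states\n",
              toupper(x$spec$flavour), length(x$t_min), ncol(x$mean)))
  invisible(x)
}
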