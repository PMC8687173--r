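pn <- cohort_parameters("normal")
pd <- cohort_parameters("t2dm")
no_meal <- meal_schedule()

test_that("gastric emptying follows the tanh profile and its limits", {
  # no meal yet: shape parameters undefined, empty-stomach limit applies
  expect_equal(gastric_emptying_rate(0, 0, pn), pn$kmax)
  expect_equal(gastric_emptying_rate(5000, 0, pn), pn$kmax)
  # kmax = kmin collapses the profile to the constant kmin
  pflat <- cohort_parameters("normal", kmax = 0.008)
  expect_equal(gastric_emptying_rate(seq(0, 37000, 1000), 37000, pflat),
               rep(0.008, 38))
  # direct evaluation at a full stomach (Qsto = D), breakfast dose
  D <- 37000
  expect_equal(gastric_emptying_rate(D, D, pn),
               pn$kmin + (pn$kmax - pn$kmin) / 2 *
                 (tanh(2.5 / (D * (1 - pn$b)) * (D - pn$b * D)) -
                    tanh(2.5 / (D * pn$c) * (D - pn$c * D)) + 2))
  expect_equal(gastric_emptying_rate(D, D, pn), 0.0555, tolerance = 1e-3)
  expect_error(gastric_emptying_rate(-1, 100, pn), "nonnegative")
  expect_error(gastric_emptying_rate(1, -1, pn), "nonnegative")
})

test_that("emptying rate stays within [kmin, kmax] over the full sweep", {
  for (p in list(pn, pd)) {
    for (D in c(37000, 74000)) {
      k <- gastric_emptying_rate(seq(0, D, length.out = 500), D, p)
      expect_true(all(k >= p$kmin))
      expect_true(all(k <= p$kmax * (1 + 1e-9)))
    }
  }
})

test_that("appearance, EGP, utilization, renal and secretion algebra", {
  # Ra = f*kabs*Qgut/BW, hand-multiplied for both cohorts
  expect_equal(rate_of_appearance(0, pn), 0)
  expect_equal(rate_of_appearance(10000, pn), 0.9 * 0.057 * 10000 / 78)
  expect_equal(rate_of_appearance(10000, pd), 0.9 * 0.023 * 10000 / 91)

  # EGP: intercept at the origin, basal point, and the clamp
  expect_equal(endogenous_glucose_production(0, 0, 0, pn), 2.7)
  expect_equal(
    endogenous_glucose_production(pn$VG * pn$Gb, pn$Ib, 6.04, pn),
    pn$EGPb, tolerance = 5e-3)
  expect_equal(endogenous_glucose_production(1e5, 1e5, 1e5, pn), 0)

  # utilization: zero at empty tissue, half-saturation, hand value
  expect_equal(glucose_utilization(0, 5, pn)$Uid, 0)
  expect_equal(glucose_utilization(pn$Km0, 0, pn)$Uid, pn$Vm0 / 2)
  expect_equal(glucose_utilization(106.16, 10, pn)$Uid,
               (2.5 + 0.47) * 106.16 / (225.59 + 106.16))
  expect_equal(glucose_utilization(50, 0, pn)$Uii, 1.0)

  # renal switch: off at/below threshold, linear above
  expect_equal(renal_excretion(100, pn), 0)
  expect_equal(renal_excretion(439, pn), 0.0005 * 100)
  expect_equal(renal_excretion(269, pd), 0)  # boundary is strict

  # hepatic extraction chain reproduces the tabulated m3 at HE = 0.6
  expect_equal(hepatic_extraction_chain(pn$Sb, pn)$HE, 0.6, tolerance = 1e-3)
  expect_equal(hepatic_extraction_chain(pn$Sb, pn)$m3, 0.285, tolerance = 1e-3)
  expect_equal(hepatic_extraction_chain(pd$Sb, pd)$m3, 0.5685, tolerance = 2e-3)
  # clipping guards the m3 pole under extreme secretion
  expect_lte(hepatic_extraction_chain(0, pn)$HE, 0.9)
  expect_gte(hepatic_extraction_chain(1e4, pn)$HE, 0.01)

  # secretion: basal portal appearance and the rising-glucose branch
  sec <- insulin_secretion(0, 6.04, 0, pn)
  expect_equal(sec$Spo, pn$Sb)
  expect_equal(sec$S, 0.5 * 6.04)
  expect_equal(insulin_secretion(2, 0, 1, pn)$Spo, 2 + 2.3 + 1.549)
  expect_equal(insulin_secretion(-10, 0, 0, pn)$Spo, 0)  # floor

  # beta-cell responsivity: equilibrium, linear zone, floored branch
  expect_equal(beta_cell_response_derivative(0, pn$Gb, pn), 0)
  expect_equal(beta_cell_response_derivative(0, pn$Gb + 10, pn),
               0.05 * 0.11 * 10)
  expect_equal(beta_cell_response_derivative(0, pn$Gb - 1000, pn),
               -0.05 * 1.549)
})

test_that("state derivative assembles the twelve balances", {
  # all-zero state, fasting: only EGP, Uii and the secretion floor act
  d0 <- state_derivative(0, rep(0, 12), no_meal, pn)
  expect_equal(unname(d0$dx[c("Qsto1", "Qsto2", "Qgut")]), c(0, 0, 0))
  expect_equal(unname(d0$dx["Gp"]), pn$kp1 - pn$Fcns)
  expect_equal(unname(d0$dx["Ipo"]),
               insulin_secretion(0, 0, d0$signals$Gdot, pn)$Spo)

  # an active meal enters the solid stomach compartment at its rate
  sch <- standard_meal_schedule()
  dm <- state_derivative(125, rep(0, 12), sch, pn)
  expect_equal(unname(dm$dx["Qsto1"]), 3700)

  # derived signals are consistent with the component functions
  x <- table_initial_state(pn)
  d <- state_derivative(0, x, no_meal, pn)
  expect_equal(d$signals$G, x[["Gp"]] / pn$VG)
  expect_equal(d$signals$I, x[["Ip"]] / pn$VI)
  expect_equal(d$signals$Gdot, unname(d$dx["Gp"]) / pn$VG)

  expect_error(state_derivative(0, c(x, 1), no_meal, pn), "length 12")
  expect_error(state_derivative(0, replace(x, 4, NaN), no_meal, pn),
               "non-finite")
})

test_that("solved basal state is an equilibrium of both cohorts", {
  for (p in list(pn, pd)) {
    b <- basal_state(p)
    d <- state_derivative(0, b, no_meal, p)$dx
    # tolerance: 1% of the basal scale, or 0.05 absolute for zero-basal states
    tol <- pmax(0.01 * abs(b), 0.05)
    expect_true(all(abs(d) <= tol))
    # and in fact essentially exact
    expect_lt(max(abs(d)), 1e-8)
    # basal glycaemia close to (but not exactly at) the tabulated Gb
    expect_equal(b[["Gp"]] / p$VG, p$Gb, tolerance = 0.05)
  }
})

test_that("fasting simulation from basal stays within 5% of basal glycaemia", {
  for (p in list(pn, pd)) {
    tr <- simulate_model(basal_state(p), no_meal, p, horizon = 1440, step = 10)
    expect_true(all(abs(tr$G_mg_dl / p$Gb - 1) < 0.05))
    # the tabulated initialization also relaxes without leaving the band
    tr2 <- simulate_model(table_initial_state(p), no_meal, p,
                          horizon = 1440, step = 10)
    expect_true(all(abs(tr2$G_mg_dl / p$Gb - 1) < 0.05))
  }
})

test_that("gut mass balance: intake = stomach + gut + absorbed", {
  tr <- simulate_model(table_initial_state(pn), standard_meal_schedule(), pn,
                       horizon = 1440, step = 1, track_balance = TRUE)
  expect_equal(tr$cum_intake[nrow(tr)], 185000)
  resid <- tr$Qsto1 + tr$Qsto2 + tr$Qgut + tr$cum_absorbed - tr$cum_intake
  expect_lt(max(abs(resid)) / 185000, 1e-6)
})

test_that("derived fluxes stay nonnegative along a meal trajectory", {
  for (p in list(pn, pd)) {
    tr <- simulate_model(table_initial_state(p), standard_meal_schedule(), p,
                         horizon = 1440, step = 5)
    for (col in c("EGP", "Ra", "Uid", "E", "S"))
      expect_true(all(tr[[col]] >= 0), label = paste(p$cohort, col))
  }
})

test_that("halving the integrator substep leaves the trajectory unchanged", {
  x0 <- table_initial_state(pn)
  sch <- standard_meal_schedule()
  a <- simulate_model(x0, sch, pn, horizon = 480, step = 10, substep = 0.1)
  b <- simulate_model(x0, sch, pn, horizon = 480, step = 10, substep = 0.05)
  scale <- vapply(STATE_NAMES, function(s) max(abs(a[[s]]), 1), numeric(1))
  for (s in STATE_NAMES)
    expect_lt(max(abs(a[[s]] - b[[s]])) / scale[[s]], 1e-6)
})

test_that("C++ and R right-hand sides agree exactly", {
  set.seed(11)
  sch <- standard_meal_schedule()
  for (i in 1:20) {
    x <- abs(rnorm(12, mean = c(5000, 3000, 2000, 140, 1, 5, 25, 25, 5, 1.5,
                                110, 2), sd = 1))
    t <- runif(1, 0, 1440)
    inp <- meal_input(sch, t)
    dR <- state_derivative(t, x, sch, pn)$dx
    dC <- glucofilt:::model_rhs_cpp(x, inp$rate, inp$D, glucofilt:::par_vector(pn))
    expect_equal(unname(dR), as.numeric(dC), tolerance = 1e-12)
  }
})

test_that("RK4 trajectory matches an independent adaptive integration", {
  skip_if_not_installed("deSolve")
  sch <- standard_meal_schedule()
  x0 <- table_initial_state(pn)
  mine <- simulate_model(x0, sch, pn, horizon = 1440, step = 1)

  rhs_desolve <- function(t, y, parms)
    list(unname(state_derivative(t, y, sch, pn)$dx))
  # integrate piecewise between meal-window boundaries so the adaptive
  # solver never steps across an input discontinuity
  breaks <- sort(unique(c(0, sch$start, sch$end, 1440)))
  out <- NULL
  y <- unname(x0)
  for (i in seq_len(length(breaks) - 1)) {
    tt <- seq(breaks[i], breaks[i + 1], by = 1)
    seg <- deSolve::ode(y, tt, rhs_desolve, NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-8)
    y <- as.numeric(seg[nrow(seg), -1])
    out <- rbind(out, if (is.null(out)) seg else seg[-1, , drop = FALSE])
  }
  ref <- out[, -1, drop = FALSE]
  ours <- as.matrix(as.data.frame(mine)[, STATE_NAMES])
  for (j in seq_len(12)) {
    scale <- max(abs(ref[, j]), 1e-6)
    expect_lt(max(abs(ours[, j] - ref[, j])) / scale, 1e-4,
              label = paste("state", STATE_NAMES[j]))
  }
})

test_that("simulate_model validates its inputs", {
  x0 <- table_initial_state(pn)
  expect_error(simulate_model(x0[-1], no_meal, pn), "length 12")
  expect_error(simulate_model(x0, no_meal, pn, horizon = -1), "positive")
  expect_error(simulate_model(x0, no_meal, pn, horizon = 10, step = 3),
               "divide")
  expect_error(simulate_model(x0, no_meal, pn, substep = 0.5), "0.1")
  tr <- simulate_model(x0, no_meal, pn, horizon = 60, step = 5)
  expect_equal(nrow(tr), 13L)  # horizon/step + 1 rows
})
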