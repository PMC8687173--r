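#' Gastric emptying rate
#'
#' Nonlinear emptying rate of the stomach as a function of the total
#' glucose mass currently in the stomach. The rate is `kmax` when the
#' stomach holds the full dose or is empty, dips towards `kmin` in
#' between, with the transition shaped by the fractions `b` and `c` of
#' the most recent dose `D`:
#' `kempt = kmin + (kmax - kmin)/2 * {tanh[a(Qsto - b D)] - tanh[b(Qsto - c D)] + 2}`
#' with `a = 2.5/(D(1-b))`, `b = 2.5/(D c)`. With no meal ingested yet
#' (`D = 0`) the shape parameters are undefined and the empty-stomach
#' limit `kmax` is returned.
#'
#' @param Qsto total stomach glucose mass (mg), nonnegative; vectorized.
#' @param D dose of the most recent meal (mg), nonnegative scalar.
#' @param params a [cohort_parameters()] object.
#' @return Emptying rate (1/min), in `[kmin, kmax]`.
#' @export
gastric_emptying_rate <- function(Qsto, D, params) {
  if (any(Qsto < 0)) stop("Qsto must be nonnegative")
  if (length(D) != 1L || D < 0) stop("D must be a nonnegative scalar")
  if (D == 0) return(rep_len(params$kmax, length(Qsto)))
  alpha <- 2.5 / (D * (1 - params$b))
  beta <- 2.5 / (D * params$c)
  params$kmin + (params$kmax - params$kmin) / 2 *
    (tanh(alpha * (Qsto - params$b * D)) -
       tanh(beta * (Qsto - params$c * D)) + 2)
}

#' Rate of glucose appearance in plasma
#'
#' The fraction `f` of intestinal glucose absorbed at rate `kabs`,
#' normalized by body weight: `Ra = f * kabs * Qgut / BW`.
#'
#' @param Qgut intestinal glucose mass (mg), nonnegative; vectorized.
#' @inheritParams gastric_emptying_rate
#' @return Appearance rate (mg/kg/min).
#' @export
rate_of_appearance <- function(Qgut, params) {
  if (any(Qgut < 0)) stop("Qgut must be nonnegative")
  params$f * params$kabs * Qgut / params$BW
}

#' Endogenous glucose production
#'
#' Hepatic glucose output, linearly suppressed by plasma glucose mass,
#' the delayed insulin signal and portal insulin, clamped at zero:
#' `EGP = max(0, kp1 - kp2*Gp - kp3*Id - kp4*Ipo)`.
#'
#' @param Gp plasma glucose mass (mg/kg).
#' @param Id delayed insulin signal (pmol/l).
#' @param Ipo portal-vein insulin mass (pmol/kg).
#' @inheritParams gastric_emptying_rate
#' @return EGP (mg/kg/min), nonnegative. Vectorized over the states.
#' @export
endogenous_glucose_production <- function(Gp, Id, Ipo, params) {
  pmax(0, params$kp1 - params$kp2 * Gp - params$kp3 * Id - params$kp4 * Ipo)
}

#' Insulin-independent and insulin-dependent glucose utilization
#'
#' `Uii` is the constant insulin-independent uptake (brain, erythrocytes;
#' `Fcns`). `Uid` is Michaelis-Menten uptake of tissue glucose with both
#' the velocity and the Michaelis constant modulated by interstitial
#' insulin action `X`:
#' `Uid = (Vm0 + Vmx*X) * Gt / (Km0 + Kmx*X + Gt)`.
#'
#' @param Gt tissue glucose mass (mg/kg), nonnegative.
#' @param X interstitial insulin action (pmol/l).
#' @inheritParams gastric_emptying_rate
#' @return List with `Uii` and `Uid` (mg/kg/min). Vectorized.
#' @export
glucose_utilization <- function(Gt, X, params) {
  if (any(Gt < 0)) stop("Gt must be nonnegative")
  Uid <- (params$Vm0 + params$Vmx * X) * Gt /
    (params$Km0 + params$Kmx * X + Gt)
  list(Uii = rep_len(params$Fcns, length(Gt)), Uid = Uid)
}

#' Renal glucose excretion
#'
#' Urinary elimination above the renal threshold:
#' `E = ke1 * (Gp - ke2)` when `Gp > ke2`, else 0.
#'
#' @inheritParams endogenous_glucose_production
#' @return Excretion rate (mg/kg/min). Vectorized over `Gp`.
#' @export
renal_excretion <- function(Gp, params) {
  if (any(Gp < 0)) stop("Gp must be nonnegative")
  ifelse(Gp > params$ke2, params$ke1 * (Gp - params$ke2), 0)
}

#' Hepatic insulin extraction and liver degradation rate
#'
#' The hepatic extraction fraction falls linearly with total secretion,
#' `HE = m6 - m5*S`, clipped to `[0.01, 0.9]` to guard the pole of the
#' liver degradation rate `m3 = HE*m1/(1 - HE)`. At basal secretion `Sb`
#' this reproduces `HEb = 0.6`.
#'
#' @param S total insulin secretion (pmol/kg/min), nonnegative.
#' @inheritParams gastric_emptying_rate
#' @return List with `HE` (dimensionless) and `m3` (1/min). Vectorized.
#' @export
hepatic_extraction_chain <- function(S, params) {
  if (any(S < 0)) stop("S must be nonnegative")
  HE <- pmin(pmax(params$m6 - params$m5 * S, 0.01), 0.9)
  list(HE = HE, m3 = HE * params$m1 / (1 - HE))
}

#' Pancreatic insulin secretion
#'
#' Total secretion is proportional to portal insulin, `S = gamma * Ipo`.
#' The portal appearance `Spo` combines the above-basal production `Y`,
#' a proportional-derivative glucose term active while glycaemia rises,
#' and the basal secretion: `Spo = Y + K*Gdot + Sb` if `Gdot > 0`, else
#' `Y + Sb`; floored at 0.
#'
#' @param Y above-basal insulin production (pmol/kg/min).
#' @param Ipo portal-vein insulin (pmol/kg), nonnegative.
#' @param Gdot time derivative of plasma glucose concentration (mg/dl/min).
#' @inheritParams gastric_emptying_rate
#' @return List with `S` and `Spo` (pmol/kg/min). Vectorized.
#' @export
insulin_secretion <- function(Y, Ipo, Gdot, params) {
  if (any(Ipo < 0)) stop("Ipo must be nonnegative")
  Spo <- pmax(0, Y + params$Sb + ifelse(Gdot > 0, params$K * Gdot, 0))
  list(S = params$gamma * Ipo, Spo = Spo)
}

#' Beta-cell responsivity dynamics
#'
#' First-order relaxation of the above-basal production `Y` towards the
#' static glucose response `B*(G - h)` (with threshold `h = Gb`), at rate
#' `A`; when the static response would undercut `-Sb` the target is
#' floored there: `dY/dt = -A*[Y - B*(G - h)]` if `B*(G - h) >= -Sb`,
#' else `-A*Y - A*Sb`.
#'
#' @param Y above-basal insulin production (pmol/kg/min).
#' @param G plasma glucose concentration (mg/dl).
#' @inheritParams gastric_emptying_rate
#' @return dY/dt (pmol/kg/min^2). Vectorized.
#' @export
beta_cell_response_derivative <- function(Y, G, params) {
  over <- params$B * (G - params$Gb)
  ifelse(over >= -params$Sb,
         -params$A * (Y - over),
         -params$A * Y - params$A * params$Sb)
}

#' Full model right-hand side
#'
#' Assembles all twelve state derivatives and the auxiliary (derived)
#' signals at time `t`. The glucose-rate term driving secretion is the
#' algebraically computed `dGp/VG` (no numerical differentiation). The
#' meal rate is the schedule's instantaneous rate at `t`.
#'
#' @param t time (min).
#' @param x named or unnamed numeric state vector of length 12 in the
#'   canonical order `r STATE_NAMES`.
#' @param schedule a [meal_schedule()].
#' @inheritParams gastric_emptying_rate
#' @return List with `dx` (named length-12 derivative) and `signals`
#'   (list: `kempt`, `Ra`, `EGP`, `Uii`, `Uid`, `E`, `G`, `I`, `HE`,
#'   `m3`, `S`, `Spo`, `Gdot`, `Vm`, `Km`, `meal_rate`, `D`).
#' @export
state_derivative <- function(t, x, schedule, params) {
  if (length(x) != 12L) stop("state vector must have length 12")
  if (any(!is.finite(x))) stop("non-finite state vector")
  x <- setNames(as.numeric(x), STATE_NAMES)
  inp <- meal_input(schedule, t)

  Qsto <- x["Qsto1"] + x["Qsto2"]
  kempt <- gastric_emptying_rate(Qsto, inp$D, params)
  Ra <- rate_of_appearance(x["Qgut"], params)
  G <- x["Gp"] / params$VG
  I <- x["Ip"] / params$VI
  EGP <- endogenous_glucose_production(x["Gp"], x["Id"], x["Ipo"], params)
  E <- renal_excretion(x["Gp"], params)
  u <- glucose_utilization(x["Gt"], x["X"], params)

  dGp <- EGP + Ra - u$Uii - E - params$k1 * x["Gp"] + params$k2 * x["Gt"]
  dGt <- -u$Uid + params$k1 * x["Gp"] - params$k2 * x["Gt"]
  Gdot <- dGp / params$VG

  sec <- insulin_secretion(x["Y"], x["Ipo"], Gdot, params)
  he <- hepatic_extraction_chain(sec$S, params)
  dY <- beta_cell_response_derivative(x["Y"], G, params)

  dx <- c(
    Qsto1 = unname(-params$kgri * x["Qsto1"] + inp$rate),
    Qsto2 = unname(-kempt * x["Qsto2"] + params$kgri * x["Qsto1"]),
    Qgut = unname(-params$kabs * x["Qgut"] + kempt * x["Qsto2"]),
    Gp = unname(dGp),
    Y = unname(dY),
    Ipo = unname(-params$gamma * x["Ipo"] + sec$Spo),
    Id = unname(-params$ki * (x["Id"] - x["I1"])),
    I1 = unname(-params$ki * (x["I1"] - I)),
    Il = unname(-(params$m1 + he$m3) * x["Il"] + params$m2 * x["Ip"] + sec$S),
    Ip = unname(-(params$m2 + params$m4) * x["Ip"] + params$m1 * x["Il"]),
    Gt = unname(dGt),
    X = unname(-params$p2u * x["X"] + params$p2u * (max(I, params$Ib) - params$Ib))
  )
  signals <- list(
    kempt = unname(kempt), Ra = unname(Ra), EGP = unname(EGP),
    Uii = unname(u$Uii), Uid = unname(u$Uid), E = unname(E),
    G = unname(G), I = unname(I), HE = unname(he$HE), m3 = unname(he$m3),
    S = unname(sec$S), Spo = unname(sec$Spo), Gdot = unname(Gdot),
    Vm = params$Vm0 + params$Vmx * unname(x["X"]),
    Km = params$Km0 + params$Kmx * unname(x["X"]),
    meal_rate = inp$rate, D = inp$D
  )
  list(dx = dx, signals = signals)
}

#' Simulate the deterministic model
#'
#' Fixed-step classical Runge-Kutta (4th order) integration of the full
#' model, with internal substeps of at most 0.1 min, meal rates sampled
#' at substep midpoints, and nonnegative states clipped at zero after
#' every substep. The trajectory is sampled every `step` minutes.
#'
#' @param x0 initial state (length 12, canonical order).
#' @param schedule a [meal_schedule()].
#' @param params a [cohort_parameters()] object.
#' @param horizon simulation length (min), default 1440 (24 h).
#' @param step output sampling interval (min); must divide `horizon`.
#' @param substep internal integrator step (min), at most 0.1.
#' @param track_balance if `TRUE`, also integrate cumulative ingested and
#'   absorbed glucose (columns `cum_intake`, `cum_absorbed`, mg) for
#'   mass-balance audits.
#' @return A data frame of class `model_trajectory`: `t_min`, the twelve
#'   states, plasma concentrations `G_mg_dl` and `I_pmol_l`, and the
#'   derived signals `EGP`, `Ra`, `Uid`, `E`, `S`.
#' @examples
#' p <- cohort_parameters("normal")
#' tr <- simulate_model(table_initial_state(p), standard_meal_schedule(), p,
#'                      horizon = 60, step = 5)
#' head(tr)
#' @export
simulate_model <- function(x0, schedule, params, horizon = 1440, step = 1,
                           substep = 0.1, track_balance = FALSE) {
  if (length(x0) != 12L) stop("x0 must have length 12")
  if (any(!is.finite(x0))) stop("x0 must be finite")
  if (horizon <= 0) stop("horizon must be positive")
  nout <- horizon / step
  if (abs(nout - round(nout)) > 1e-9) stop("step must divide horizon")
  nout <- as.integer(round(nout))
  if (substep > 0.1 + 1e-12) stop("substep must be at most 0.1 min")

  nr <- if (track_balance) 14L else 12L
  states <- matrix(0, nrow = nout + 1L, ncol = nr)
  x <- matrix(c(as.numeric(x0), numeric(nr - 12L)), ncol = 1L)
  states[1L, ] <- x
  mm <- meal_matrix(schedule)
  pv <- par_vector(params)
  for (k in seq_len(nout)) {
    x <- rk4_propagate(x, (k - 1) * step, step, substep, mm, pv)
    states[k + 1L, ] <- x
  }
  times <- seq(0, horizon, by = step)
  traj_frame(times, states, schedule, params)
}

# assemble the exported trajectory data frame with derived signals
traj_frame <- function(times, states, schedule, params) {
  out <- data.frame(t_min = times)
  st <- states[, 1:12, drop = FALSE]
  colnames(st) <- STATE_NAMES
  out <- cbind(out, as.data.frame(st))
  out$G_mg_dl <- st[, "Gp"] / params$VG
  out$I_pmol_l <- st[, "Ip"] / params$VI
  out$EGP <- endogenous_glucose_production(st[, "Gp"], st[, "Id"],
                                           st[, "Ipo"], params)
  out$Ra <- rate_of_appearance(st[, "Qgut"], params)
  out$Uid <- glucose_utilization(st[, "Gt"], st[, "X"], params)$Uid
  out$E <- renal_excretion(st[, "Gp"], params)
  out$S <- params$gamma * st[, "Ipo"]
  if (ncol(states) == 14L) {
    out$cum_intake <- states[, 13L]
    out$cum_absorbed <- states[, 14L]
  }
  class(out) <- c("model_trajectory", "data.frame")
  out
}
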