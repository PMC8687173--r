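#' Tabulated overnight-fasted initial state
#'
#' The standard initialization of truths and filters: empty stomach and
#' intestine, basal glycaemia, basal insulin signals. Concentration-valued
#' entries are converted to the mass units of the dynamic equations
#' (`Gp = G0 * VG` mg/kg, `Ip = I0 * VI` pmol/kg).
#'
#' @param params a [cohort_parameters()] object.
#' @return Named numeric vector of length 12 in canonical state order.
#' @export
table_initial_state <- function(params) {
  tab <- switch(params$cohort,
    normal = c(G0 = 75.18, Ipo = 6.04, Id = 25.56, I1 = 25.56,
               Il = 4.57, I0 = 25.56, Gt = 106.16),
    t2dm = c(G0 = 181.47, Ipo = 6.38, Id = 59.88, I1 = 59.88,
             Il = 5.95, I0 = 59.88, Gt = 144.46),
    stop("no tabulated initial state for cohort '", params$cohort, "'")
  )
  setNames(c(0, 0, 0, tab[["G0"]] * params$VG, 0, tab[["Ipo"]],
             tab[["Id"]], tab[["I1"]], tab[["Il"]],
             tab[["I0"]] * params$VI, tab[["Gt"]], 0),
           STATE_NAMES)
}

#' Solve the model's fasting steady state
#'
#' Computes the self-consistent equilibrium of the dynamics with no meal
#' input: the unique state at which every derivative vanishes. The insulin
#' chain is resolved in closed form given the glycaemia `G`, the tissue
#' glucose balance is solved by a root search, and the outer glucose
#' balance closes a scalar root problem in `G`.
#'
#' Note that this solved basal point differs slightly from the tabulated
#' initialization ([table_initial_state()]): the tabulated portal insulin
#' is not an exact fixed point of the adopted secretion dynamics, so a
#' simulation started from the table relaxes to this equilibrium within
#' tens of minutes.
#'
#' @inheritParams table_initial_state
#' @param interval search bracket for the equilibrium glycaemia (mg/dl).
#' @return Named numeric vector of length 12 with all derivatives below
#'   1e-8 in magnitude.
#' @export
basal_state <- function(params, interval = c(30, 600)) {
  insulin_chain <- function(G) {
    over <- params$B * (G - params$Gb)
    Y <- max(over, -params$Sb)
    Spo <- max(0, Y + params$Sb)
    Ipo <- Spo / params$gamma
    S <- params$gamma * Ipo
    he <- hepatic_extraction_chain(S, params)
    denom <- (params$m1 + he$m3) -
      params$m1 * params$m2 / (params$m2 + params$m4)
    Il <- S / denom
    Ip <- params$m1 * Il / (params$m2 + params$m4)
    I <- Ip / params$VI
    list(Y = Y, Ipo = Ipo, S = S, Il = Il, Ip = Ip, I = I,
         X = max(0, I - params$Ib))
  }
  tissue_eq <- function(Gp, X) {
    upper <- params$k1 * Gp / params$k2
    if (upper <= 0) return(0)
    g <- function(Gt) params$k1 * Gp - params$k2 * Gt -
      glucose_utilization(Gt, X, params)$Uid
    uniroot(g, c(0, upper), tol = 1e-12)$root
  }
  residual <- function(G) {
    ins <- insulin_chain(G)
    Gp <- G * params$VG
    Gt <- tissue_eq(Gp, ins$X)
    u <- glucose_utilization(Gt, ins$X, params)
    endogenous_glucose_production(Gp, ins$I, ins$Ipo, params) -
      params$Fcns - renal_excretion(Gp, params) - u$Uid
  }
  G <- uniroot(residual, interval, tol = 1e-12)$root
  ins <- insulin_chain(G)
  Gp <- G * params$VG
  Gt <- tissue_eq(Gp, ins$X)
  setNames(c(0, 0, 0, Gp, ins$Y, ins$Ipo, ins$I, ins$I, ins$Il, ins$Ip,
             Gt, ins$X), STATE_NAMES)
}
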