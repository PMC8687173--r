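#' Model parameter sets for the glucose-insulin meal model
#'
#' Returns the full constant set for one virtual-patient cohort: glucose and
#' insulin kinetics, meal appearance, endogenous glucose production (EGP),
#' utilization, beta-cell secretion and renal elimination. Two built-in
#' profiles are shipped, `"normal"` (healthy, BW 78 kg) and `"t2dm"`
#' (type 2 diabetes mellitus, BW 91 kg). Any field can be overridden.
#'
#' Units: volumes `VG` (dl/kg) and `VI` (l/kg); `Gb` (mg/dl) is both the
#' basal glycaemia and the secretion threshold `h`; rate constants are
#' 1/min; `m5` min*kg/pmol; `kp1`, `EGPb`, `Fcns`, `Vm0` mg/kg/min;
#' `kp3` mg/kg/min per pmol/l; `kp4` mg/kg/min per pmol/kg; `Km0`, `Kmx`,
#' `ke2` mg/kg; `K` pmol/kg per mg/dl; `B` pmol/kg/min per mg/dl;
#' `Sb` pmol/kg/min; `f`, `b`, `c`, `m6`, `HEb` dimensionless; `BW` kg.
#'
#' @param cohort `"normal"` or `"t2dm"`.
#' @param ... named scalar overrides of individual fields (e.g. `BW = 80`).
#' @return An object of class `model_parameters`: a named list of scalars
#'   plus the `cohort` label, validated for positivity and internal
#'   consistency (in particular `HEb = m6 - m5*Sb` to 1e-3).
#' @examples
#' p <- cohort_parameters("normal")
#' p$m6 - p$m5 * p$Sb   # basal hepatic extraction, 0.6
#' @export
cohort_parameters <- function(cohort = c("normal", "t2dm"), ...) {
  cohort <- match.arg(cohort)
  base <- .parameter_profiles[[cohort]]
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(base))
    if (length(bad))
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
    base[names(over)] <- over
  }
  p <- c(list(cohort = cohort), base)
  class(p) <- "model_parameters"
  validate_parameters(p)
  p
}

# Built-in cohort profiles (rate constants 1/min unless noted).
.parameter_profiles <- list(
  normal = list(
    VG = 1.88, Gb = 75.177, k1 = 0.065, k2 = 0.079,
    VI = 0.05, Ib = 25.556,
    m1 = 0.190, m2 = 0.484, m3_basal = 0.285, m4 = 0.194,
    m5 = 0.0304, m6 = 0.6471, HEb = 0.6, Sb = 1.549,
    kmax = 0.0558, kmin = 0.008, kabs = 0.057, kgri = 0.0558,
    f = 0.9, b = 0.82, c = 0.01,
    kp1 = 2.7, kp2 = 0.0021, kp3 = 0.009, kp4 = 0.0618,
    ki = 0.0079, EGPb = 1.8,
    Fcns = 1.0, Vm0 = 2.5, Vmx = 0.047, Km0 = 225.59, Kmx = 0,
    p2u = 0.0331,
    K = 2.3, A = 0.05, B = 0.11, gamma = 0.5,
    ke1 = 0.0005, ke2 = 339, BW = 78
  ),
  t2dm = list(
    VG = 1.49, Gb = 181.4737, k1 = 0.042, k2 = 0.071,
    VI = 0.04, Ib = 59.875,
    m1 = 0.379, m2 = 0.673, m3_basal = 0.5685, m4 = 0.269,
    m5 = 0.0526, m6 = 0.8118, HEb = 0.6, Sb = 4.027,
    kmax = 0.0465, kmin = 0.0076, kabs = 0.023, kgri = 0.0465,
    f = 0.9, b = 0.68, c = 0.09,
    kp1 = 3.09, kp2 = 0.0007, kp3 = 0.005, kp4 = 0.0786,
    ki = 0.0066, EGPb = 2.1,
    Fcns = 1.0, Vm0 = 4.65, Vmx = 0.034, Km0 = 466.21, Kmx = 0,
    p2u = 0.0840,
    K = 0.99, A = 0.013, B = 0.05, gamma = 0.5,
    ke1 = 0.0007, ke2 = 269, BW = 91
  )
)

validate_parameters <- function(p) {
  pos <- c("VG", "Gb", "k1", "k2", "VI", "Ib", "m1", "m2", "m3_basal", "m4",
           "m5", "m6", "Sb", "kmax", "kmin", "kabs", "kgri", "kp1", "ki",
           "EGPb", "Fcns", "Vm0", "Km0", "p2u", "K", "A", "B", "gamma",
           "ke1", "ke2", "BW")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a strictly positive scalar")
  }
  for (nm in c("kp2", "kp3", "kp4", "Vmx", "Kmx")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("parameter '", nm, "' must be a nonnegative scalar")
  }
  for (nm in c("f", "b", "c", "HEb")) {
    v <- p[[nm]]
    if (v <= 0 || v >= 1)
      stop("parameter '", nm, "' must lie in (0, 1)")
  }
  if (p$b <= p$c) stop("gastric-emptying shape requires b > c")
  if (p$kmax < p$kmin) stop("kmax must be >= kmin")
  if (abs(p$HEb - (p$m6 - p$m5 * p$Sb)) >= 1e-3)
    stop("inconsistent secretion block: HEb must equal m6 - m5*Sb (to 1e-3)")
  invisible(p)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Glucose-insulin model parameters, cohort:", x$cohort,
      sprintf("(BW %g kg)\n", x$BW))
  flds <- setdiff(names(x), "cohort")
  vals <- unlist(x[flds])
  print(vals, ...)
  invisible(x)
}

# Flat numeric vector in the fixed order the C++ integrator expects.
par_vector <- function(p) {
  c(p$VG, p$Gb, p$k1, p$k2, p$VI, p$Ib,
    p$m1, p$m2, p$m4, p$m5, p$m6, p$Sb,
    p$kmax, p$kmin, p$kabs, p$kgri, p$f, p$b, p$c,
    p$kp1, p$kp2, p$kp3, p$kp4, p$ki,
    p$Fcns, p$Vm0, p$Vmx, p$Km0, p$Kmx, p$p2u,
    p$K, p$A, p$B, p$gamma, p$ke1, p$ke2, p$BW)
}
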