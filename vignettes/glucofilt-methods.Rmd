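---
title: "Estimating unmeasured glucose and insulin states from plasma glucose alone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating unmeasured glucose and insulin states from plasma glucose alone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucofilt)
```

## Scope

`glucofilt` couples a twelve-state physiological model of glucose–insulin
homoeostasis with meal intake to two Gaussian sigma-point Bayesian filters,
so that every unmeasured state — stomach, gut, plasma and tissue glucose;
portal, liver, plasma and interstitial insulin signals — can be estimated
from a noisy plasma-glucose measurement stream. This vignette records the
model and its assumptions, the numerical choices, the design decisions that
were genuinely open, and what the synthetic benchmark does and does not
demonstrate.

## The model

### Glucose subsystem

A meal enters the solid stomach compartment `Qsto1` at a finite ingestion
rate, is ground into the liquid compartment `Qsto2` at rate `kgri`, empties
into the gut at the state-dependent rate `kempt(Qsto)`, and is absorbed at
rate `kabs`, a fraction `f` reaching plasma:

* `dQsto1/dt = −kgri·Qsto1 + r(t)`
* `dQsto2/dt = −kempt·Qsto2 + kgri·Qsto1`
* `dQgut/dt = −kabs·Qgut + kempt·Qsto2`, with `Ra = f·kabs·Qgut/BW`.

The emptying rate is the tanh profile
`kempt = kmin + (kmax−kmin)/2·{tanh[α(Qsto−bD)] − tanh[β(Qsto−cD)] + 2}`
with `α = 2.5/(D(1−b))`, `β = 2.5/(Dc)` and `D` the most recent dose: the
stomach empties fastest when nearly full or nearly empty and slowest in
between. Plasma and tissue glucose masses exchange at rates `k1`, `k2`;
plasma gains endogenous production `EGP = kp1 − kp2·Gp − kp3·Id − kp4·Ipo`
(clamped at zero) and loses the constant insulin-independent uptake
`Fcns`, renal excretion `ke1·(Gp−ke2)` above the threshold, and the
insulin-dependent Michaelis–Menten uptake
`Uid = (Vm0+Vmx·X)·Gt/(Km0+Kmx·X+Gt)` from the tissue compartment.

### Insulin subsystem and secretion

Portal insulin `Ipo` relaxes at rate `γ` towards the portal appearance
`Spo = Y + K·Ġ + Sb` while glycaemia rises (`Y + Sb` otherwise, floored at
zero); total secretion is `S = γ·Ipo`. The liver extracts the fraction
`HE = m6 − m5·S` per pass (clipped to `[0.01, 0.9]` to guard the pole of
`m3 = HE·m1/(1−HE)`), and liver/plasma insulin masses exchange through
`m1`, `m2` with degradation `m3`, `m4`. Two first-order delays `I1`, `Id`
carry the plasma concentration `I = Ip/VI` to the EGP term, and the remote
action `X` relaxes towards `I − Ib` at rate `p2u`.

### Choices the source material left open

Four points required a decision; they are encoded once and not exposed as
tuning knobs:

* **Meal input.** The impulse `D·δ(t)` formulation is replaced by a finite
  ingestion rate (3.7 g/min), so a 37 g breakfast occupies a 10-min window
  and the daily intake integrates exactly to 185 g. Before any meal
  (`D = 0`) the emptying-rate shape parameters are undefined and the
  empty-stomach limit `kempt = kmax` applies.
* **Utilization numerator.** `Uid` uses tissue glucose `Gt`, the only
  choice dimensionally consistent with `Km` in mg/kg.
* **Production dynamics.** The above-basal production `Y` follows the
  first-order responsivity `dY/dt = −A·[Y − B·(G−h)]` with threshold
  `h = Gb` and the target floored at `−Sb`, which is what the secretion
  parameter block (`A`, `B`, `h`) implies.
* **Units.** All dynamics run in mass units (`Gp`, `Gt` mg/kg; `Ip`, `Il`,
  `Ipo` pmol/kg); tabulated concentration-valued initial conditions are
  converted through `VG` and `VI`. The renal threshold `ke2` is compared
  against `Gp` in mg/kg. The `X` drive uses `max(I, Ib) − Ib` so that the
  action variable cannot run negative at basal.

### The basal point

`basal_state()` solves the fasting steady state exactly (closed-form
insulin chain given glycaemia, nested root searches for the glucose
balance); the returned state zeroes every derivative to machine precision
and sits within ~4% of the tabulated basal glycaemia for both cohorts
(77.6 vs 75.2 mg/dl normal; 174.9 vs 181.5 mg/dl diabetic). The
conventional tabulated initialization (`table_initial_state()`) is *not*
an exact equilibrium — its portal-insulin entry is inconsistent with the
basal secretion relation `Ipo = Sb/γ`, so a fasting simulation started
there relaxes towards the solved equilibrium within tens of minutes,
without leaving a ±5% band around basal glycaemia. The experiment keeps
the tabulated values as the truth/filter initialization, exactly as the
benchmark prescribes; equilibrium assertions use the solved basal point.

## Numerical integration

The integrator is fixed-step classical RK4 with substeps of 0.1 min
(implemented in C++; an R reference right-hand side is tested against it
to 1e-12, and the full 24 h trajectory against an independent adaptive
solver to 1e-4 relative). Two details matter:

* **Meal-rate sampling.** The ingestion rate is sampled at each substep
  midpoint and held constant across the four RK4 stages. Because meal
  windows align with the substep grid, cumulative intake is exact and the
  gut mass balance `Qsto1+Qsto2+Qgut + absorbed = ingested` holds to
  machine precision, rather than the ~0.1% error a stage-sampled
  discontinuous input would produce.
* **Clipping.** Physically nonnegative states are clipped at zero after
  every substep and after every process-noise draw (`Y` and `X` may be
  transiently negative). The model's switches — the EGP clamp, the renal
  threshold, the rising-glucose secretion branch — are evaluated pointwise
  inside the right-hand side; they are bounded discontinuities of the
  derivative only, and the 0.1-min step is short relative to every time
  constant in the model, so no event location is needed.

## The filters

Both filters represent the state belief as a Gaussian and differ only in
the quadrature point set:

* **Unscented:** `2n+1 = 25` points at the mean and along the columns of
  the lower Cholesky factor of `(n+κ)P`, with `W0 = κ/(n+κ)` and
  `Wi = 1/(2(n+κ))`. The recommended `κ = 3−n` is `−9` at `n = 12`, so
  the centre weight is `−3`: the recombined covariance can lose positive
  semi-definiteness, and a repair path (symmetric eigenvalue floor at
  1e-10) backs the Cholesky factorization everywhere.
* **Cubature quadrature:** the `2n` unit-hypersphere axis points scaled by
  `sqrt(2χᵢ)` for each of the `n′` roots `χᵢ` of the generalized
  Gauss–Laguerre polynomial at `α = n/2−1` (`2n·n′ = 48` points at
  `n′ = 2`). Nodes and weights come from the Golub–Welsch symmetric
  tridiagonal eigenproblem; the point weights are the radial quadrature
  factors normalized to sum to one, a normalization fixed by the Gaussian
  moment-matching identities (the rule reproduces the mean, covariance
  and fourth radial moment `n(n+2)` exactly) rather than by typography.
  With `n′ = 1` the set reduces to the familiar third-degree cubature
  rule `x̂ ± √n·Lᵢ` with equal weights.

Prediction propagates every point through the deterministic dynamics over
one sampling interval and adds `Q` (continuous dynamics, discrete additive
noise — the same convention the truth generator uses). Because the
measurement is linear (`H` selects plasma glucose mass), the correction is
the exact linear Kalman update; a sigma-point measurement transform would
add an approximation layer and nothing else. On any linear system both
filters collapse to the analytic Kalman filter, which the test suite
verifies to 1e-8.

## The benchmark

`experiment_config()` encodes the study conditions: 24 h horizon, 1-min
sampling, meals of 37/74/74 g at 3.7 g/min starting at t = 120, 420 and
960 min (8 AM, 1 PM, 10 PM on a 6 AM clock), process noise
`Q = diag(1, 0.1×11)`, measurement noise `R = 16` in (mg/kg)² of plasma
glucose mass, initial covariance
`P0 = diag(400², 0.1, 0.1, 0.1, 200², 0.3, 100, 10, 10, 30, 0.1, 0.5)`,
50 Monte-Carlo runs. Truth trajectories add a `N(0, Q)` draw per 1-min
step; measurements add `N(0, R)` from an independent stream; each trial's
filter mean is drawn from `N(init, P0)` (a deterministic mean-start mode
exists for tests). Trial `j` of a study with base seed `s` uses seed
`s+j`, split into documented process/measurement/initialization
sub-streams, so the whole experiment is a pure function of the
configuration and one integer — and both filters see identical
realizations. Per-state RMSE across trials is reported per time step,
summarized after a 60-min burn-in (the transient during which the filter
digests its deliberately inflated `P0`).

Problem sizes used in the shipped test suite: the full dual-filter,
dual-cohort, 50-run study (the scale at which the RMSE claims are made)
plus reduced 2-run configurations for interface checks; the noise
calibration of the truth generator uses a 10 000-step law-of-large-numbers
sweep.

## What the synthetic study shows — and what it does not

The benchmark demonstrates *filter* properties: both filters hold the
post-burn-in plasma-glucose RMSE well under the 4 mg/kg measurement noise
floor on both cohorts, remain stable (finite, PSD posteriors at all 1440
steps) despite the negative unscented centre weight, and recover states
that are never measured. It is a twin experiment: the truth is generated
by the same model family the filter carries, so it says nothing about
structural model error against real patients. Real CGM noise is neither
white nor Gaussian, real meals are not pure glucose at a constant rate,
and parameter variability between individuals is represented only crudely
by additive process noise. Those are the gaps between this benchmark and
a clinical claim.

## Known limitations

* The diabetic cohort's solved fasting equilibrium sits ≈3.6% below its
  tabulated basal glycaemia; the tabulated initialization is kept for the
  benchmark but is not a fixed point of the dynamics (see above).
* `X` (insulin action) is weakly observable from plasma glucose alone; its
  RMSE is dominated by the prior and the process noise, and should be read
  as such.
* No exogenous insulin pharmacokinetics, no oral hypoglycaemic agents, no
  closed-loop dosing: the package estimates states, it does not control
  them. A type-1 variant (removing endogenous secretion) is structurally
  easy but not provided.
* The relative wall-clock ratio of the two filters (≈2, from 48 vs 25
  point propagations) is reported for information only; it is
  hardware-dependent and never asserted.
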