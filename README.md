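# glucofilt

Sigma-point state estimation for a glucose–insulin meal model.

## The problem

In diabetes care almost everything a clinician would like to track —
glucose still in the stomach and gut after a meal, glucose taken up by
tissue, insulin in the portal vein, the liver and the interstitium — cannot
be measured in routine practice. What *can* be measured, noisily and at
regular intervals, is plasma glucose. `glucofilt` reconstructs all of the
unmeasured quantities from that single noisy signal, for both healthy and
type-2-diabetic virtual patients, by fusing a physiological model of
glucose–insulin homoeostasis with the measurements through Gaussian
sigma-point Bayesian filters. This is the state-estimation layer an
artificial pancreas or a dosing advisor would sit on top of.

## The model and the filters

The physiology is a twelve-state meal-intake homoeostasis model. The state
vector is

```
x = [Qsto1, Qsto2, Qgut, Gp, Y, Ipo, Id, I1, Il, Ip, Gt, X]
```

— solid/liquid stomach glucose and gut glucose (mg); plasma and tissue
glucose mass (mg/kg); above-basal insulin production Y (pmol/kg/min);
portal, liver and plasma insulin mass (pmol/kg); delayed insulin signals
Id, I1 and insulin action X (pmol/l). The key fluxes:

* gastric emptying with the tanh-shaped rate
  `kempt(Qsto) = kmin + (kmax−kmin)/2 · {tanh[α(Qsto−bD)] − tanh[β(Qsto−cD)] + 2}`,
* appearance in plasma `Ra = f·kabs·Qgut/BW`,
* endogenous glucose production `EGP = kp1 − kp2·Gp − kp3·Id − kp4·Ipo`
  (clamped at 0),
* insulin-dependent utilization `Uid = (Vm0+Vmx·X)·Gt/(Km0+Kmx·X+Gt)`,
* renal excretion `E = ke1·(Gp − ke2)` above the threshold `ke2`,
* secretion `S = γ·Ipo` with hepatic extraction `HE = m6 − m5·S` and
  `m3 = HE·m1/(1−HE)`.

Two built-in parameter profiles (`"normal"`, `"t2dm"`) supply all
constants, volumes and basal values, including body weights of 78 and
91 kg.

Estimation is the discrete-time filtering problem `ẋ = f(x) + ω`,
`ω ~ N(0, Q)`, with scalar measurements `y_k = H x_k + v_k`,
`v_k ~ N(0, R)`, where `H` selects plasma glucose mass. Two
Gaussian-assumed-density filters are implemented:

* **UKF** — the unscented transform's `2n+1 = 25` sigma points with
  scaling `κ = 3 − n = −9`;
* **CQKF** — the cubature quadrature rule: `2n·n′ = 48` points built from
  the unit-hypersphere axis directions and the roots of the generalized
  Gauss–Laguerre polynomial of order `n′ = 2` at `α = n/2 − 1`.

Both propagate their points through the model dynamics (fixed-step RK4,
implemented in C++) and apply the exact linear Kalman correction.
Performance is quantified by per-state Monte-Carlo RMSE,
`RMSE_k = sqrt((1/M) Σ_j (x_{j,k} − x̂_{j,k})²)`, over `M = 50` runs of a
24 h, 1-min-sampled study with three meals (37 + 74 + 74 g at 3.7 g/min).

## Worked example

```r
library(glucofilt)

p  <- cohort_parameters("normal")
tr <- simulate_model(table_initial_state(p), standard_meal_schedule(), p)
max(tr$G_mg_dl)
#> [1] 141.6163

cfg <- experiment_config("normal", mc_runs = 5, seed = 1)
compare_filters(cfg)
#> Filter comparison over 5 Monte-Carlo runs
#> Time-averaged post-burn-in RMSE per state:
#>       Qsto1  Qsto2   Qgut     Gp      Y    Ipo     Id     I1     Il     Ip
#> ukf  2.2593 5.1258 2.4144 1.2922 1.0305 1.6481 3.7277 3.9980 3.4853 1.0017
#> cqkf 2.2379 4.9508 2.3790 1.3147 1.1475 1.6852 3.7809 3.9715 3.5518 1.0196
#>          Gt      X
#> ukf  1.4143 7.0165
#> cqkf 1.4421 7.0971
#> Relative wall-clock time (CQKF / UKF): 1.89
```

The healthy virtual patient peaks at ≈142 mg/dl after lunch and returns
towards the ≈75 mg/dl basal level between meals. Both filters hold the
post-burn-in plasma-glucose RMSE near 1.3 mg/kg — far below the 4 mg/kg
measurement noise floor — while recovering the never-measured states
(stomach and gut glucose to within a few mg, tissue glucose to
≈1.4 mg/kg). The wall-clock ratio is informational: the CQKF propagates
48 points against the UKF's 25, and costs roughly twice as much.

A thin command-line front end with subcommands `simulate`, `estimate`,
`rmse` and `compare` ships at `inst/cli/glucofilt.R`; configurations can
be given as flat YAML files (see `load_config()`).

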