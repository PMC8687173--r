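#include <Rcpp.h>
using namespace Rcpp;

// Parameter vector layout; must match par_vector() in R/parameters.R.
enum Par {
  VG, GB, K1, K2, VI, IB,
  M1, M2, M4, M5, M6, SB,
  KMAX, KMIN, KABS, KGRI, Ff, Bb, Cc,
  KP1, KP2, KP3, KP4, KI,
  FCNS, VM0, VMX, KM0, KMX, P2U,
  Kresp, Aa, Bresp, GAMMA, KE1, KE2, BW,
  NPAR
};

// State layout (0-based): 0 Qsto1, 1 Qsto2, 2 Qgut, 3 Gp, 4 Y, 5 Ipo,
// 6 Id, 7 I1, 8 Il, 9 Ip, 10 Gt, 11 X. Rows 12/13, when present, carry
// cumulative ingested and cumulative absorbed glucose (mass-balance audit).
static const int NEG_OK[2] = {4, 11};  // Y and X may go negative

static inline double clip(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Model right-hand side for one state column; r = current meal rate
// (mg/min), D = dose of the most recent meal (mg).
static void rhs(const double *x, double *dx, double r, double D,
                const double *p, int nextra) {
  const double Qsto = x[0] + x[1];
  double kempt;
  if (D > 0.0) {
    const double alpha = 2.5 / (D * (1.0 - p[Bb]));
    const double beta  = 2.5 / (D * p[Cc]);
    kempt = p[KMIN] + 0.5 * (p[KMAX] - p[KMIN]) *
      (std::tanh(alpha * (Qsto - p[Bb] * D)) -
       std::tanh(beta  * (Qsto - p[Cc] * D)) + 2.0);
  } else {
    kempt = p[KMAX];
  }

  const double Ra  = p[Ff] * p[KABS] * x[2] / p[BW];
  const double G   = x[3] / p[VG];
  const double I   = x[9] / p[VI];
  double EGP = p[KP1] - p[KP2] * x[3] - p[KP3] * x[6] - p[KP4] * x[5];
  if (EGP < 0.0) EGP = 0.0;
  const double E   = x[3] > p[KE2] ? p[KE1] * (x[3] - p[KE2]) : 0.0;
  const double Uii = p[FCNS];
  const double Uid = (p[VM0] + p[VMX] * x[11]) * x[10] /
                     (p[KM0] + p[KMX] * x[11] + x[10]);

  const double dGp = EGP + Ra - Uii - E - p[K1] * x[3] + p[K2] * x[10];
  const double dGt = -Uid + p[K1] * x[3] - p[K2] * x[10];
  const double Gdot = dGp / p[VG];

  const double S  = p[GAMMA] * x[5];
  const double HE = clip(p[M6] - p[M5] * S, 0.01, 0.9);
  const double m3 = HE * p[M1] / (1.0 - HE);

  double Spo = x[4] + p[SB] + (Gdot > 0.0 ? p[Kresp] * Gdot : 0.0);
  if (Spo < 0.0) Spo = 0.0;

  const double over = p[Bresp] * (G - p[GB]);  // h = Gb
  double dY;
  if (over >= -p[SB]) dY = -p[Aa] * (x[4] - over);
  else                dY = -p[Aa] * x[4] - p[Aa] * p[SB];

  const double Idrive = (I > p[IB] ? I : p[IB]) - p[IB];

  dx[0]  = -p[KGRI] * x[0] + r;
  dx[1]  = -kempt * x[1] + p[KGRI] * x[0];
  dx[2]  = -p[KABS] * x[2] + kempt * x[1];
  dx[3]  = dGp;
  dx[4]  = dY;
  dx[5]  = -p[GAMMA] * x[5] + Spo;
  dx[6]  = -p[KI] * (x[6] - x[7]);
  dx[7]  = -p[KI] * (x[7] - I);
  dx[8]  = -(p[M1] + m3) * x[8] + p[M2] * x[9] + S;
  dx[9]  = -(p[M2] + p[M4]) * x[9] + p[M1] * x[8];
  dx[10] = dGt;
  dx[11] = -p[P2U] * x[11] + p[P2U] * Idrive;
  if (nextra >= 1) dx[12] = r;                          // cumulative intake
  if (nextra >= 2) dx[13] = p[KABS] * x[2];             // cumulative absorption
}

// Meal rate / most-recent dose at time t. Windows are [start, end).
static void meal_at(const NumericMatrix &meals, double t,
                    double *r, double *D) {
  *r = 0.0; *D = 0.0;
  for (int i = 0; i < meals.nrow(); ++i) {
    if (meals(i, 0) <= t) {
      *D = meals(i, 3);
      if (t < meals(i, 1)) *r = meals(i, 2);
    }
  }
}

// [[Rcpp::export]]
NumericVector model_rhs_cpp(NumericVector x, double r, double D,
                            NumericVector par) {
  if (x.size() != 12) stop("state must have length 12");
  if (par.size() != NPAR) stop("parameter vector has wrong length");
  NumericVector dx(12);
  rhs(REAL(x), REAL(dx), r, D, REAL(par), 0);
  return dx;
}

// Propagate columns of X (12 or 14 rows) from t0 over `horizon` minutes by
// fixed-step classical RK4 with step `substep`. The meal rate is sampled at
// each substep midpoint and held constant across the four stages, so the
// cumulative ingested mass is exact when meal windows align with the substep
// grid. Nonnegative states are clipped at 0 after every substep.
// [[Rcpp::export]]
NumericMatrix rk4_propagate(NumericMatrix X, double t0, double horizon,
                            double substep, NumericMatrix meals,
                            NumericVector par) {
  const int nr = X.nrow(), nc = X.ncol();
  if (nr != 12 && nr != 14) stop("state matrix must have 12 or 14 rows");
  if (par.size() != NPAR) stop("parameter vector has wrong length");
  const int nextra = nr - 12;
  const int nsub = (int) std::lround(horizon / substep);
  if (nsub < 1 || std::fabs(nsub * substep - horizon) > 1e-9)
    stop("substep must divide the propagation horizon");
  const double h = horizon / nsub;
  const double *p = REAL(par);

  NumericMatrix out(clone(X));
  std::vector<double> k1(nr), k2(nr), k3(nr), k4(nr), tmp(nr);

  for (int s = 0; s < nsub; ++s) {
    const double t = t0 + s * h;
    double r, D;
    meal_at(meals, t + 0.5 * h, &r, &D);
    for (int j = 0; j < nc; ++j) {
      double *x = &out(0, j);
      rhs(x, k1.data(), r, D, p, nextra);
      for (int i = 0; i < nr; ++i) tmp[i] = x[i] + 0.5 * h * k1[i];
      rhs(tmp.data(), k2.data(), r, D, p, nextra);
      for (int i = 0; i < nr; ++i) tmp[i] = x[i] + 0.5 * h * k2[i];
      rhs(tmp.data(), k3.data(), r, D, p, nextra);
      for (int i = 0; i < nr; ++i) tmp[i] = x[i] + h * k3[i];
      rhs(tmp.data(), k4.data(), r, D, p, nextra);
      for (int i = 0; i < nr; ++i)
        x[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      for (int i = 0; i < 12; ++i) {
        if (i == NEG_OK[0] || i == NEG_OK[1]) continue;
        if (x[i] < 0.0) x[i] = 0.0;
      }
      for (int i = 0; i < nr; ++i) {
        if (!std::isfinite(x[i]))
          stop("integration produced a non-finite value in state %d at t = %f",
               i + 1, t + h);
      }
    }
  }
  return out;
}
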