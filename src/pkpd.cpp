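// Computational backend for the two-compartment oral PK model with lag,
// the effect-compartment sigmoid inhibitory Emax response, and the FOCE
// population objective.  Closed-form (tri-exponential) model evaluation
// keeps the doubly-nested estimation loops fast; the numeric ODE route in
// R/deSolve serves as the independent cross-check.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double PROP_ERROR_FLOOR = 1e-6; // mg/L, variance floor for proportional error

// PK parameter vector layout: (Ka, V, V2, CL, CL2, Tlag)
// PD parameter vector layout: (Ke0, IC50, Gam, E0)

// Disposition eigenvalues (alpha >= beta) of the two-compartment system.
static void disposition(const double *pk, double &alpha, double &beta,
                        double &k10, double &k12, double &k21) {
  k10 = pk[3] / pk[1];
  k12 = pk[4] / pk[1];
  k21 = pk[4] / pk[2];
  double s = k10 + k12 + k21;
  double disc = s * s - 4.0 * k10 * k21;
  disc = disc > 0.0 ? std::sqrt(disc) : 0.0;
  alpha = 0.5 * (s + disc);
  beta = 0.5 * (s - disc);
}

// Exponential coefficients of A1(t) = sum_j a_j * exp(-lam_j * tau),
// tau = t - Tlag, for a unit bolus into the depot at tau = 0.
// Returns false when Ka coincides with a disposition eigenvalue (degenerate).
static bool a1_coefficients(const double *pk, double dose, double lam[3],
                            double a[3], double tol) {
  double alpha, beta, k10, k12, k21;
  disposition(pk, alpha, beta, k10, k12, k21);
  double ka = pk[0];
  lam[0] = alpha;
  lam[1] = beta;
  lam[2] = ka;
  double scale = std::max(ka, alpha);
  if (std::fabs(ka - alpha) < tol * scale || std::fabs(ka - beta) < tol * scale ||
      std::fabs(alpha - beta) < tol * std::max(alpha, 1e-300)) {
    return false;
  }
  double kad = ka * dose;
  a[0] = kad * (k21 - alpha) / ((ka - alpha) * (beta - alpha));
  a[1] = kad * (k21 - beta) / ((ka - beta) * (alpha - beta));
  a[2] = kad * (k21 - ka) / ((alpha - ka) * (beta - ka));
  return true;
}

// Nudge Ka away from a disposition eigenvalue so the tri-exponential form
// stays usable inside the estimation loops (relative perturbation 1e-9,
// far below the estimation noise floor).
static void coefficients_robust(const double *pk_in, double dose, double lam[3],
                                double a[3]) {
  double pk[6];
  std::copy(pk_in, pk_in + 6, pk);
  for (int tries = 0; tries < 8; ++tries) {
    if (a1_coefficients(pk, dose, lam, a, 1e-10)) return;
    pk[0] *= 1.0 + 1e-9 * (tries + 1.0);
    pk[2] *= 1.0 + 7e-10 * (tries + 1.0);
  }
  stop("degenerate PK rate constants (Ka equal to a disposition eigenvalue)");
}

// Central concentration at times t (strict: error on degeneracy).
static void conc_eval(const double *pk, double dose, const double *t, int m,
                      double *out, bool strict) {
  double lam[3], a[3];
  if (strict) {
    if (!a1_coefficients(pk, dose, lam, a, 1e-10))
      stop("degenerate PK rate constants (Ka equal to a disposition eigenvalue)");
  } else {
    coefficients_robust(pk, dose, lam, a);
  }
  double V = pk[1], tlag = pk[5];
  for (int j = 0; j < m; ++j) {
    double tau = t[j] - tlag;
    if (tau <= 0.0 || dose == 0.0) {
      out[j] = 0.0;
    } else {
      double s = a[0] * std::exp(-lam[0] * tau) + a[1] * std::exp(-lam[1] * tau) +
                 a[2] * std::exp(-lam[2] * tau);
      out[j] = std::max(s / V, 0.0);
    }
  }
}

// Effect-site concentration: Ce' = Ke0 * (C - Ce), Ce(0) = 0.
static void ce_eval(const double *pk, double ke0, double dose, const double *t,
                    int m, double *out, bool strict) {
  double lam[3], a[3];
  if (strict) {
    if (!a1_coefficients(pk, dose, lam, a, 1e-10))
      stop("degenerate PK rate constants (Ka equal to a disposition eigenvalue)");
  } else {
    coefficients_robust(pk, dose, lam, a);
  }
  double V = pk[1], tlag = pk[5];
  for (int j = 0; j < m; ++j) {
    double tau = t[j] - tlag;
    if (tau <= 0.0 || dose == 0.0) {
      out[j] = 0.0;
      continue;
    }
    double ce = 0.0;
    for (int i = 0; i < 3; ++i) {
      double d = ke0 - lam[i];
      if (std::fabs(d) < 1e-9 * std::max(ke0, 1.0)) {
        ce += a[i] * ke0 * tau * std::exp(-ke0 * tau);
      } else {
        ce += a[i] * ke0 * (std::exp(-lam[i] * tau) - std::exp(-ke0 * tau)) / d;
      }
    }
    out[j] = std::max(ce / V, 0.0);
  }
}

static double effect_one(double ce, double ic50, double gam, double e0) {
  if (ce <= 0.0) return e0;
  // compute on the log scale for numerical range safety
  double r = std::exp(gam * (std::log(ce) - std::log(ic50)));
  return e0 * (1.0 - r / (1.0 + r));
}

// ---- exported model evaluators -------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conc(NumericVector pk, double dose, NumericVector t,
                       bool strict = false) {
  NumericVector out(t.size());
  conc_eval(REAL(pk), dose, REAL(t), t.size(), REAL(out), strict);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_ce(NumericVector pk, double ke0, double dose,
                     NumericVector t, bool strict = false) {
  NumericVector out(t.size());
  ce_eval(REAL(pk), ke0, dose, REAL(t), t.size(), REAL(out), strict);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_effect(NumericVector ce, double ic50, double gam, double e0) {
  NumericVector out(ce.size());
  for (R_xlen_t j = 0; j < ce.size(); ++j)
    out[j] = effect_one(ce[j], ic50, gam, e0);
  return out;
}

// ---- joint likelihood -----------------------------------------------------

struct StageProblem {
  int stage;            // 1 = pk (proportional error), 2 = pd (additive error)
  const double *tv;     // stage 1: tv pk(6); stage 2: tv pd(4)
  const double *pkfix;  // stage 2 only: the subject's fixed PK params (6)
  const int *active;    // indices (0-based) of parameters carrying eta
  const double *omega;  // variances of the active etas
  int p;                // number of active etas
  double sigma;
  double dose;
  const double *t;
  const double *y;
  int m;
};

static void predict(const StageProblem &pr, const double *eta, double *f) {
  if (pr.stage == 1) {
    double pk[6];
    std::copy(pr.tv, pr.tv + 6, pk);
    for (int k = 0; k < pr.p; ++k) pk[pr.active[k]] *= std::exp(eta[k]);
    conc_eval(pk, pr.dose, pr.t, pr.m, f, false);
  } else {
    double pd[4];
    std::copy(pr.tv, pr.tv + 4, pd);
    for (int k = 0; k < pr.p; ++k) pd[pr.active[k]] *= std::exp(eta[k]);
    std::vector<double> ce(pr.m);
    ce_eval(pr.pkfix, pd[0], pr.dose, pr.t, pr.m, ce.data(), false);
    for (int j = 0; j < pr.m; ++j) f[j] = effect_one(ce[j], pd[1], pd[2], pd[3]);
  }
}

// negative joint log-likelihood: -[ log p(y | eta) + log p(eta) ]
static double neg_joint(const StageProblem &pr, const double *eta) {
  std::vector<double> f(pr.m);
  predict(pr, eta, f.data());
  double nll = 0.0;
  for (int j = 0; j < pr.m; ++j) {
    double sd = pr.stage == 1
                    ? pr.sigma * std::max(f[j], PROP_ERROR_FLOOR)
                    : pr.sigma;
    double r = pr.y[j] - f[j];
    nll += 0.5 * std::log(2.0 * M_PI * sd * sd) + 0.5 * r * r / (sd * sd);
  }
  for (int k = 0; k < pr.p; ++k) {
    nll += 0.5 * std::log(2.0 * M_PI * pr.omega[k]) +
           0.5 * eta[k] * eta[k] / pr.omega[k];
  }
  return nll;
}

// ---- compact Nelder-Mead (dimension <= 4) --------------------------------

template <typename F>
static double nelder_mead(F fn, std::vector<double> &x, double step,
                          double ftol, int maxeval) {
  const int n = (int)x.size();
  const double rho = 1.0, chi = 2.0, gam = 0.5, sig = 0.5;
  int np = n + 1, neval = 0;
  std::vector<std::vector<double> > S(np, x);
  std::vector<double> fv(np);
  for (int i = 1; i < np; ++i) S[i][i - 1] += step;
  for (int i = 0; i < np; ++i) { fv[i] = fn(S[i].data()); ++neval; }
  std::vector<double> xc(n), xr(n), xe(n), xk(n);
  while (neval < maxeval) {
    // order
    std::vector<int> idx(np);
    for (int i = 0; i < np; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(), [&](int a, int b) { return fv[a] < fv[b]; });
    std::vector<std::vector<double> > S2(np);
    std::vector<double> fv2(np);
    for (int i = 0; i < np; ++i) { S2[i] = S[idx[i]]; fv2[i] = fv[idx[i]]; }
    S.swap(S2); fv.swap(fv2);
    if (std::fabs(fv[np - 1] - fv[0]) <=
        ftol * (std::fabs(fv[0]) + ftol)) break;
    // centroid of best n
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += S[i][j];
      xc[j] = s / n;
    }
    for (int j = 0; j < n; ++j) xr[j] = xc[j] + rho * (xc[j] - S[np - 1][j]);
    double fr = fn(xr.data()); ++neval;
    if (fr < fv[0]) {
      for (int j = 0; j < n; ++j) xe[j] = xc[j] + chi * (xr[j] - xc[j]);
      double fe = fn(xe.data()); ++neval;
      if (fe < fr) { S[np - 1] = xe; fv[np - 1] = fe; }
      else { S[np - 1] = xr; fv[np - 1] = fr; }
    } else if (fr < fv[np - 2]) {
      S[np - 1] = xr; fv[np - 1] = fr;
    } else {
      bool outside = fr < fv[np - 1];
      if (outside)
        for (int j = 0; j < n; ++j) xk[j] = xc[j] + gam * (xr[j] - xc[j]);
      else
        for (int j = 0; j < n; ++j) xk[j] = xc[j] - gam * (xc[j] - S[np - 1][j]);
      double fk = fn(xk.data()); ++neval;
      if (fk < std::min(fr, fv[np - 1])) {
        S[np - 1] = xk; fv[np - 1] = fk;
      } else { // shrink towards best
        for (int i = 1; i < np; ++i) {
          for (int j = 0; j < n; ++j) S[i][j] = S[0][j] + sig * (S[i][j] - S[0][j]);
          fv[i] = fn(S[i].data()); ++neval;
        }
      }
    }
  }
  int best = 0;
  for (int i = 1; i < np; ++i) if (fv[i] < fv[best]) best = i;
  x = S[best];
  return fv[best];
}

// ---- Laplace/FOCE subject contribution -----------------------------------

// log-determinant of a symmetric positive-definite matrix (p <= 4) via
// Cholesky; ridge-regularizes on failure (near-flat individual likelihood).
static double logdet_spd(std::vector<double> &H, int p) {
  for (int attempt = 0; attempt < 6; ++attempt) {
    std::vector<double> L(H);
    bool ok = true;
    double ld = 0.0;
    for (int i = 0; i < p && ok; ++i) {
      for (int j = 0; j <= i; ++j) {
        double s = L[i * p + j];
        for (int k = 0; k < j; ++k) s -= L[i * p + k] * L[j * p + k];
        if (i == j) {
          if (s <= 0.0) { ok = false; break; }
          L[i * p + i] = std::sqrt(s);
          ld += 2.0 * std::log(L[i * p + i]);
        } else {
          L[i * p + j] = s / L[j * p + j];
        }
      }
    }
    if (ok) return ld;
    double ridge = std::pow(10.0, attempt - 8.0);
    for (int i = 0; i < p; ++i) H[i * p + i] += ridge;
  }
  return 0.0; // unreachable in practice
}

// -2 log of the FOCE-approximate marginal likelihood for one subject.
// Gauss-Newton (first-order) Hessian of the joint log-likelihood at the
// conditional mode: H = F' R^-1 F + Omega^-1, with the residual variance R
// evaluated at the mode (interaction for the proportional PK error).
static double subject_m2ll(const StageProblem &pr, double *eta_warm,
                           double inner_ftol, int inner_maxeval) {
  const int p = pr.p;
  if (p == 0) return 2.0 * neg_joint(pr, NULL);
  int tlag_slot = -1; // position of the Tlag eta, if active (PK stage)
  for (int k = 0; k < p; ++k)
    if (pr.stage == 1 && pr.active[k] == 5) tlag_slot = k;

  std::vector<double> eta(eta_warm, eta_warm + p);
  auto fn = [&](const double *e) { return neg_joint(pr, e); };
  double nll_hat = nelder_mead(fn, eta, 0.3, inner_ftol, inner_maxeval);
  // polish from zero in case the warm start tracked a poor mode
  bool warm_nonzero = false;
  for (int k = 0; k < p; ++k) warm_nonzero = warm_nonzero || eta_warm[k] != 0.0;
  if (warm_nonzero) {
    std::vector<double> eta0(p, 0.0);
    double nll0 = nelder_mead(fn, eta0, 0.3, inner_ftol, inner_maxeval);
    if (nll0 < nll_hat) { eta = eta0; nll_hat = nll0; }
  }
  // The individual likelihood is flat (floored proportional error) while
  // the subject's lag exceeds its first positive observation time, which
  // strands mode searches started above the cliff.  Add a start with the
  // lag pulled just below the first observation.
  if (pr.stage == 1 && tlag_slot >= 0 && pr.m > 0) {
    double tvT = pr.tv[5];
    if (tvT > 0.0) {
      double target = std::log(0.85 * pr.t[0] / tvT);
      if (target < 0.0) {
        std::vector<double> etaT(p, 0.0);
        etaT[tlag_slot] = std::max(target, -4.0);
        double nllT = nelder_mead(fn, etaT, 0.3, inner_ftol, inner_maxeval);
        if (nllT < nll_hat) { eta = etaT; nll_hat = nllT; }
      }
    }
  }
  std::copy(eta.begin(), eta.end(), eta_warm);

  // model sensitivities F = df/deta at the mode (central differences)
  const double h = 1e-4;
  std::vector<double> fhat(pr.m), fp(pr.m), fm(pr.m), F((size_t)pr.m * p);
  predict(pr, eta.data(), fhat.data());
  std::vector<double> e(eta);
  for (int k = 0; k < p; ++k) {
    e[k] = eta[k] + h; predict(pr, e.data(), fp.data());
    e[k] = eta[k] - h; predict(pr, e.data(), fm.data());
    e[k] = eta[k];
    for (int j = 0; j < pr.m; ++j) F[(size_t)j * p + k] = (fp[j] - fm[j]) / (2.0 * h);
  }
  std::vector<double> H((size_t)p * p, 0.0);
  for (int j = 0; j < pr.m; ++j) {
    double sd = pr.stage == 1
                    ? pr.sigma * std::max(fhat[j], PROP_ERROR_FLOOR)
                    : pr.sigma;
    double w = 1.0 / (sd * sd);
    for (int a = 0; a < p; ++a)
      for (int b = 0; b <= a; ++b)
        H[(size_t)a * p + b] += w * F[(size_t)j * p + a] * F[(size_t)j * p + b];
  }
  for (int a = 0; a < p; ++a) {
    H[(size_t)a * p + a] += 1.0 / pr.omega[a];
    for (int b = a + 1; b < p; ++b) H[(size_t)a * p + b] = H[(size_t)b * p + a];
  }
  double ld = logdet_spd(H, p);
  return 2.0 * nll_hat + ld - p * std::log(2.0 * M_PI);
}

// [[Rcpp::export]]
double cpp_joint_nll(int stage, NumericVector tv, NumericVector pkfix,
                     IntegerVector active, NumericVector omega, double sigma,
                     double dose, NumericVector t, NumericVector y,
                     NumericVector eta) {
  StageProblem pr;
  pr.stage = stage;
  pr.tv = REAL(tv);
  pr.pkfix = pkfix.size() ? REAL(pkfix) : NULL;
  pr.active = active.size() ? INTEGER(active) : NULL;
  pr.omega = omega.size() ? REAL(omega) : NULL;
  pr.p = active.size();
  pr.sigma = sigma;
  pr.dose = dose;
  pr.t = REAL(t);
  pr.y = REAL(y);
  pr.m = t.size();
  return neg_joint(pr, eta.size() ? REAL(eta) : NULL);
}

// FOCE -2 log-likelihood summed over subjects.
// Flattened data layout: subject i owns rows starts[i]..starts[i+1]-1
// (0-based) of times/ys; warm is the n x p matrix of inner-mode starting
// values, updated in place with the empirical Bayes modes.
// [[Rcpp::export]]
List cpp_foce(int stage, NumericVector tv, IntegerVector active,
              NumericVector omega, double sigma, NumericVector doses,
              IntegerVector starts, NumericVector times, NumericVector ys,
              NumericMatrix pkmat, NumericMatrix warm,
              double inner_ftol = 1e-11, int inner_maxeval = 600) {
  const int n = doses.size();
  const int p = active.size();
  NumericVector per(n);
  double total = 0.0;
  std::vector<double> eta(p);
  for (int i = 0; i < n; ++i) {
    StageProblem pr;
    pr.stage = stage;
    pr.tv = REAL(tv);
    pr.pkfix = stage == 2 ? &pkmat(0, i) : NULL; // pkmat is 6 x n (col = subject)
    pr.active = p ? INTEGER(active) : NULL;
    pr.omega = p ? REAL(omega) : NULL;
    pr.p = p;
    pr.sigma = sigma;
    pr.dose = doses[i];
    pr.t = REAL(times) + starts[i];
    pr.y = REAL(ys) + starts[i];
    pr.m = starts[i + 1] - starts[i];
    for (int k = 0; k < p; ++k) eta[k] = warm(i, k);
    double v = subject_m2ll(pr, p ? eta.data() : NULL, inner_ftol, inner_maxeval);
    for (int k = 0; k < p; ++k) warm(i, k) = eta[k];
    per[i] = v;
    total += v;
  }
  return List::create(_["objective"] = total, _["per_subject"] = per,
                      _["eta"] = warm);
}
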