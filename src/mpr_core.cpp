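// Core numerical routines for the penalized Weibull MPR model.
//
// The model: h(t | tau_i, gamma_i) = tau_i * gamma_i * t^(gamma_i - 1) with
// log tau_i = x_i' beta, log gamma_i = z_i' alpha.  The penalized
// log-likelihood is l(theta) = l0(theta) - n * sum_j J_lambda_j(a(theta_j))
// where a(x) = sqrt(x^2 + eps^2) - eps is the smoothed absolute value.
//
// Everything here operates on the (standardized) design matrices handed over
// from R; standardization and back-transformation live on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double sabs(double x, double eps)  { return std::sqrt(x * x + eps * eps) - eps; }
static inline double sabs1(double x, double eps) { return x / std::sqrt(x * x + eps * eps); }
static inline double sabs2(double x, double eps) {
  double s = eps * eps + x * x;
  return eps * eps / (s * std::sqrt(s));
}

// Penalty J(a(theta); lambda) and derivatives with respect to theta.
// family: 0 = lasso form (also used for the adaptive lasso, whose weights are
// folded into the per-coefficient lambda), 1 = SCAD with knot parameter a.
// d2 is the exact second derivative (used in the information matrix for the
// sandwich covariance and effective df); d2mm is the positive-definite
// MM/LQA surrogate curvature J'(a(theta)) / sqrt(theta^2 + eps^2) used only
// inside the Newton solve (same gradient, hence same stationary points, but
// no sign-overshoot of shrunk coefficients).
static void pen_d(double th, double lam, int family, double a_scad, double eps,
                  double &J, double &d1, double &d2, double &d2mm) {
  if (lam <= 0.0) { J = 0.0; d1 = 0.0; d2 = 0.0; d2mm = 0.0; return; }
  double u = sabs(th, eps), u1 = sabs1(th, eps), u2 = sabs2(th, eps);
  double Ju, Ju1, Ju2;
  if (family == 0) {
    Ju = lam * u; Ju1 = lam; Ju2 = 0.0;
  } else {
    if (u <= lam) {
      Ju = lam * u; Ju1 = lam; Ju2 = 0.0;
    } else if (u < a_scad * lam) {
      Ju  = (2.0 * a_scad * lam * u - u * u - lam * lam) / (2.0 * (a_scad - 1.0));
      Ju1 = (a_scad * lam - u) / (a_scad - 1.0);
      Ju2 = -1.0 / (a_scad - 1.0);
    } else {
      Ju = lam * lam * (a_scad + 1.0) / 2.0; Ju1 = 0.0; Ju2 = 0.0;
    }
  }
  J = Ju;
  d1 = Ju1 * u1;
  d2 = Ju2 * u1 * u1 + Ju1 * u2;
  d2mm = Ju1 / std::sqrt(th * th + eps * eps);
}

struct Derivs {
  double ll0 = 0.0, obj = 0.0;
  vec grad, grad0;
  mat I, I0, Imm;
  unsigned int n_clip = 0;
};

// order: 0 = objective only, 1 = + gradients, 2 = + information matrices
static void mpr_derivs(const mat &X, const mat &Z, const vec &lt, const vec &del,
                       const vec &lamb, const vec &lama, int family, double a_scad,
                       double eps, double clip, const vec &th, int order, Derivs &D) {
  const int n = X.n_rows, pb = X.n_cols, pa = Z.n_cols;
  vec b = th.subvec(0, pb - 1), a = th.subvec(pb, pb + pa - 1);
  vec etb = X * b, eta = Z * a;
  D.n_clip = accu(abs(etb) > clip) + accu(abs(eta) > clip);
  etb = clamp(etb, -clip, clip);
  eta = clamp(eta, -clip, clip);
  vec g = exp(eta);
  vec glt = g % lt;
  // tau * t^gamma = exp(etb + gamma * log t), guarded against overflow
  vec tg = exp(clamp(etb + glt, -700.0, 700.0));
  D.ll0 = accu(del % (etb + eta + glt - lt) - tg);
  double penv = 0.0;
  vec Vb(pb, fill::zeros), Va(pa, fill::zeros);
  vec Sb(pb, fill::zeros), Sa(pa, fill::zeros);
  vec Mb(pb, fill::zeros), Ma(pa, fill::zeros);
  for (int j = 0; j < pb; j++) {
    double J, d1, d2, dm;
    pen_d(b(j), lamb(j), family, a_scad, eps, J, d1, d2, dm);
    penv += J; Vb(j) = d1; Sb(j) = d2; Mb(j) = dm;
  }
  for (int j = 0; j < pa; j++) {
    double J, d1, d2, dm;
    pen_d(a(j), lama(j), family, a_scad, eps, J, d1, d2, dm);
    penv += J; Va(j) = d1; Sa(j) = d2; Ma(j) = dm;
  }
  D.obj = D.ll0 - n * penv;
  if (order < 1) return;
  vec Ub = del - tg;
  vec Ua = del % (1.0 + glt) - tg % glt;
  D.grad0 = join_cols(X.t() * Ub, Z.t() * Ua);
  D.grad = D.grad0 - n * join_cols(Vb, Va);
  if (order < 2) return;
  vec wb  = tg;
  vec wa  = (tg % (glt + 1.0) - del) % glt;
  vec wab = tg % glt;
  mat Ibb = X.t() * (X.each_col() % wb);
  mat Iaa = Z.t() * (Z.each_col() % wa);
  mat Iba = X.t() * (Z.each_col() % wab);
  D.I0 = join_cols(join_rows(Ibb, Iba), join_rows(Iba.t(), Iaa));
  D.I = D.I0;
  D.Imm = D.I0;
  for (int j = 0; j < pb; j++) {
    D.I(j, j)   += n * Sb(j);
    D.Imm(j, j) += n * Mb(j);
  }
  for (int j = 0; j < pa; j++) {
    D.I(pb + j, pb + j)   += n * Sa(j);
    D.Imm(pb + j, pb + j) += n * Ma(j);
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_mpr_derivs(const arma::mat &X, const arma::mat &Z,
                          const arma::vec &time, const arma::vec &status,
                          const arma::vec &lamb, const arma::vec &lama,
                          int family, double a_scad, double eps, double clip,
                          const arma::vec &theta, int order) {
  Derivs D;
  mpr_derivs(X, Z, log(time), status, lamb, lama, family, a_scad, eps, clip,
             theta, order, D);
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loglik") = D.ll0,
      Rcpp::Named("objective") = D.obj,
      Rcpp::Named("n_clip") = (int)D.n_clip);
  if (order >= 1) {
    out["gradient"] = D.grad;
    out["gradient0"] = D.grad0;
  }
  if (order >= 2) {
    out["information"] = D.I;
    out["information0"] = D.I0;
  }
  return out;
}

// Penalized Newton-Raphson with step-halving.  The linear system uses the
// MM-surrogate penalty curvature (positive definite); the exact penalized
// gradient drives the iteration, so fixed points solve the score equations.
// [[Rcpp::export]]
Rcpp::List cpp_mpr_newton(const arma::mat &X, const arma::mat &Z,
                          const arma::vec &time, const arma::vec &status,
                          const arma::vec &lamb, const arma::vec &lama,
                          int family, double a_scad, double eps, double clip,
                          const arma::vec &init, int max_iter, double tol) {
  vec lt = log(time);
  vec th = init;
  Derivs D;
  mpr_derivs(X, Z, lt, status, lamb, lama, family, a_scad, eps, clip, th, 2, D);
  double obj = D.obj;
  unsigned int clip_total = D.n_clip;
  int it = 0, n_ridge = 0;
  bool conv = false;
  double delta = datum::inf;
  for (it = 1; it <= max_iter; it++) {
    vec step;
    bool ok = solve(step, D.Imm, D.grad, solve_opts::likely_sympd + solve_opts::no_approx);
    double ridge = 1e-8;
    while (!ok && ridge < 1e8) {
      // Levenberg-style diagonal inflation for an indefinite/singular system
      mat Ij = D.Imm;
      Ij.diag() += ridge * (1.0 + abs(Ij.diag()));
      ok = solve(step, Ij, D.grad, solve_opts::no_approx);
      ridge *= 100.0;
      n_ridge++;
    }
    if (!ok) break;
    double h = 1.0;
    Derivs Dn;
    vec thn;
    for (int k = 0; ; k++) {
      thn = th + h * step;
      mpr_derivs(X, Z, lt, status, lamb, lama, family, a_scad, eps, clip, thn, 0, Dn);
      if (std::isfinite(Dn.obj) && Dn.obj >= obj - 1e-12 * (1.0 + std::abs(obj)))
        break;
      h *= 0.5;
      if (k >= 25) { thn = th; break; }  // no ascent direction found
    }
    delta = max(abs(thn - th));
    th = thn;
    mpr_derivs(X, Z, lt, status, lamb, lama, family, a_scad, eps, clip, th, 2, D);
    obj = D.obj;
    clip_total += D.n_clip;
    if (delta < tol) { conv = true; break; }
  }
  return Rcpp::List::create(
      Rcpp::Named("theta") = th,
      Rcpp::Named("converged") = conv,
      Rcpp::Named("n_iter") = std::min(it, max_iter),
      Rcpp::Named("objective") = obj,
      Rcpp::Named("loglik") = D.ll0,
      Rcpp::Named("gradient") = D.grad,
      Rcpp::Named("information") = D.I,
      Rcpp::Named("information0") = D.I0,
      Rcpp::Named("last_step") = delta,
      Rcpp::Named("n_ridge") = n_ridge,
      Rcpp::Named("n_clip") = (int)clip_total);
}
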