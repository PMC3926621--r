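// Spectral projected-gradient basis pursuit denoise: LASSO subproblems
// solved by nonmonotone SPG with Barzilai-Borwein steps, l1 radius driven
// to the Pareto root by Newton's method (the SPGL1 scheme).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <algorithm>

using namespace arma;

namespace {

// Euclidean projection onto the l1 ball of radius tau.
vec proj_l1(const vec& v, double tau) {
  if (tau <= 0) return zeros<vec>(v.n_elem);
  vec av = abs(v);
  if (accu(av) <= tau) return v;
  std::vector<double> u(av.begin(), av.end());
  std::sort(u.begin(), u.end(), std::greater<double>());
  double cs = 0, theta = 0;
  uword rho = 0;
  for (uword k = 0; k < u.size(); ++k) {
    cs += u[k];
    double t = (cs - tau) / (k + 1);
    if (u[k] > t) { rho = k + 1; theta = t; }
  }
  (void)rho;
  vec out = av - theta;
  out.transform([](double x) { return x > 0 ? x : 0.0; });
  return sign(v) % out;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List bpdn_spg_cpp(const arma::mat& A, const arma::vec& y, double sigma,
                        double opt_tol, double bp_tol, int max_matvec,
                        int max_inner, int max_outer) {
  const uword K = A.n_cols;
  const double ynorm = norm(y);
  if (ynorm == 0 || sigma >= ynorm) {
    return Rcpp::List::create(
        Rcpp::_["coef"] = Rcpp::NumericVector(K),
        Rcpp::_["residual_norm"] = ynorm, Rcpp::_["l1_norm"] = 0.0,
        Rcpp::_["matvec"] = 0, Rcpp::_["outer_iters"] = 0,
        Rcpp::_["converged"] = true);
  }
  const double resid_target =
      sigma > 0 ? sigma + opt_tol * std::max(1.0, ynorm)
                : std::max(bp_tol * ynorm, 1e-12);

  double tau = 0;
  vec x = zeros<vec>(K);
  vec r = y;
  double phi = ynorm;
  vec atr = A.t() * r;
  int mv = 1, outer = 0;
  bool converged = false;
  const int mem = 10;

  while (outer < max_outer) {
    ++outer;
    double gsup = norm(atr, "inf");
    double tau_new = tau + (phi - sigma) * phi / gsup;
    if (tau_new <= tau) tau_new = tau * 1.1 + 1e-12;
    tau = tau_new;

    // --- SPG on min 0.5||y-Ax||^2 s.t. ||x||_1 <= tau, warm started ---
    x = proj_l1(x, tau);
    r = y - A * x;
    double f = 0.5 * dot(r, r);
    atr = A.t() * r;
    mv += 2;
    std::vector<double> fmem(mem, f);
    double step = std::min(1.0, 1.0 / std::max(norm(atr, "inf"), 1e-300));
    for (int it = 0; it < max_inner; ++it) {
      double gap = tau * norm(atr, "inf") - dot(x, atr);
      if (gap <= opt_tol * std::max(1.0, f)) break;
      if (std::sqrt(2 * f) <= resid_target) break;
      if (mv >= max_matvec) break;
      vec g = -atr;
      double alpha = step;
      vec xn, rn;
      double fn;
      double fmax = *std::max_element(fmem.begin(), fmem.end());
      for (;;) {
        xn = proj_l1(x - alpha * g, tau);
        rn = y - A * xn;
        ++mv;
        fn = 0.5 * dot(rn, rn);
        if (fn <= fmax + 1e-4 * dot(g, xn - x) || alpha < 1e-14) break;
        alpha /= 2;
      }
      vec atrn = A.t() * rn;
      ++mv;
      vec s = xn - x;
      double sty = dot(s, (-atrn) - g);
      step = sty > 0 ? std::min(std::max(dot(s, s) / sty, 1e-10), 1e10) : 1e10;
      x = xn;
      r = rn;
      f = fn;
      atr = atrn;
      fmem.erase(fmem.begin());
      fmem.push_back(f);
    }
    phi = std::sqrt(2 * (0.5 * dot(r, r)));
    if (phi <= resid_target) { converged = true; break; }
    if (mv >= max_matvec) break;
  }
  return Rcpp::List::create(
      Rcpp::_["coef"] = Rcpp::NumericVector(x.begin(), x.end()),
      Rcpp::_["residual_norm"] = phi,
      Rcpp::_["l1_norm"] = accu(abs(x)), Rcpp::_["matvec"] = mv,
      Rcpp::_["outer_iters"] = outer, Rcpp::_["converged"] = converged);
}
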