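// EM inner loop for the four-component Gaussian mixture with
// design-constrained means.  Mirrors the reference R implementation
// (em_core_r); the R wrapper validates inputs and raises errors.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// One M-step from aggregated responsibilities.  avec/bvec/cvec are the
// per-(class, component) sums of w, w*y and w*y^2 in Xall row order.
static bool mstep(const arma::mat& Xall, const arma::uvec& free_idx,
                  const arma::vec& avec, const arma::vec& bvec,
                  const arma::vec& cvec, int n,
                  arma::vec& beta, double& sigma2, arma::vec& muv) {
  arma::mat Xf = Xall.cols(free_idx);
  arma::mat XtWX = Xf.t() * (Xf.each_col() % avec);
  arma::vec XtWy = Xf.t() * bvec;
  arma::vec bf;
  bool ok = arma::solve(bf, XtWX, XtWy, arma::solve_opts::no_approx);
  if (!ok) return false;
  beta.zeros(Xall.n_cols);
  beta.elem(free_idx) = bf;
  muv = Xall * beta;
  sigma2 = arma::accu(cvec - 2.0 * (muv % bvec) + (muv % muv) % avec) / n;
  if (sigma2 < 1e-12) sigma2 = 1e-12;
  return true;
}

// [[Rcpp::export(name = ".em_core_cpp")]]
List em_core_cpp(const arma::vec& y, const arma::mat& P,
                 const arma::mat& Xall, const arma::ivec& icls0,
                 const arma::uvec& free1, double tol, int max_iter,
                 bool has_init, const arma::vec& beta_init,
                 double sigma2_init) {
  const int n = y.n_elem;
  const int K = P.n_cols;            // 4 components
  const int LK = Xall.n_rows;        // classes * components
  arma::uvec free_idx = free1 - 1;   // to 0-based
  arma::vec y2 = y % y;

  arma::vec beta;
  double sigma2 = 0.0;
  arma::vec muv;
  bool singular = false;

  // aggregate a weight matrix W into per-(class, component) sums
  arma::vec avec(LK), bvec(LK), cvec(LK);
  auto aggregate = [&](const arma::mat& W) {
    avec.zeros(); bvec.zeros(); cvec.zeros();
    for (int i = 0; i < n; ++i) {
      const int base = icls0[i] * K;
      for (int j = 0; j < K; ++j) {
        const double w = W(i, j);
        avec[base + j] += w;
        bvec[base + j] += w * y[i];
        cvec[base + j] += w * y2[i];
      }
    }
  };

  if (has_init) {
    beta = beta_init;
    sigma2 = sigma2_init;
    muv = Xall * beta;
  } else {
    aggregate(P);
    if (!mstep(Xall, free_idx, avec, bvec, cvec, n, beta, sigma2, muv)) {
      singular = true;
    }
  }

  arma::mat W(n, K);
  std::vector<double> trace;
  double ll = -std::numeric_limits<double>::infinity();
  bool converged = false;
  int iter = 0;

  auto estep = [&]() -> double {
    const double inv2s = 1.0 / sigma2;
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      const int base = icls0[i] * K;
      double rs = 0.0;
      for (int j = 0; j < K; ++j) {
        const double m = muv[base + j];
        const double d = P(i, j) * std::exp((y[i] * m - 0.5 * m * m -
                                             0.5 * y2[i]) * inv2s);
        W(i, j) = d;
        rs += d;
      }
      for (int j = 0; j < K; ++j) W(i, j) /= rs;
      s += std::log(rs);
    }
    return s - 0.5 * n * std::log(2.0 * M_PI * sigma2);
  };

  if (!singular) {
    ll = estep();
    trace.push_back(ll);
    while (iter < max_iter) {
      ++iter;
      aggregate(W);
      if (!mstep(Xall, free_idx, avec, bvec, cvec, n, beta, sigma2, muv)) {
        singular = true;
        break;
      }
      double ll_new = estep();
      trace.push_back(ll_new);
      if (std::isfinite(ll_new) && ll_new - ll < tol) {
        converged = ll_new - ll > -1e-6;
        ll = ll_new;
        break;
      }
      ll = ll_new;
    }
  }

  return List::create(
    _["beta"] = beta, _["sigma2"] = sigma2, _["loglik"] = ll,
    _["n_iter"] = iter, _["converged"] = converged, _["weights"] = W,
    _["loglik_trace"] = trace, _["singular"] = singular);
}
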