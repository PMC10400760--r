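#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the weighted elastic net along a lambda path.
//
// Objective (glmnet parameterisation), with v_i = w_i / sum(w):
//   (1/2) sum_i v_i (y_i - x_i' b)^2 + lambda * (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)
//
// X must arrive standardized to weighted mean 0 and weighted mean-square 1 per
// column, y centered to weighted mean 0; the R wrapper owns the
// (de)standardization and the intercept. Warm starts along the descending
// path; an active-set sweep after each full pass keeps the inner loop cheap.
// For moderate p the "covariance update" form is used: the weighted gradient
// g = X'V(y - Xb) is maintained from the Gram matrix G = X'VX, making each
// coordinate update O(p) instead of O(n).

inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export]]
List cd_elastic_net_path(const NumericMatrix& X, const NumericVector& y,
                         const NumericVector& v, const NumericVector& lambda,
                         double alpha, double tol, int max_iter) {
  const int n = X.nrow(), p = X.ncol(), nlam = lambda.size();
  NumericMatrix beta_path(p, nlam);
  IntegerVector iters(nlam);
  LogicalVector converged(nlam);

  // covariance mode: precompute q = X'Vy and G = X'VX (O(n p^2), then each
  // sweep is O(p^2) independent of n). Falls back to residual updates when
  // the Gram matrix would be too large.
  const bool cov_mode = p <= 512;

  std::vector<double> beta(p, 0.0);
  std::vector<bool> active(p, false);
  std::vector<double> resid, g, q, G;

  if (cov_mode) {
    q.assign(p, 0.0);
    G.assign((size_t)p * p, 0.0);
    std::vector<double> vx(n);
    for (int j = 0; j < p; ++j) {
      const double* xj = &X(0, j);
      double qj = 0.0;
      for (int i = 0; i < n; ++i) { vx[i] = v[i] * xj[i]; qj += vx[i] * y[i]; }
      q[j] = qj;
      for (int k = j; k < p; ++k) {
        const double* xk = &X(0, k);
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += vx[i] * xk[i];
        G[(size_t)j * p + k] = s;
        G[(size_t)k * p + j] = s;
      }
    }
    g = q;  // gradient at beta = 0
  } else {
    resid.resize(n);
    for (int i = 0; i < n; ++i) resid[i] = y[i];
  }

  for (int l = 0; l < nlam; ++l) {
    const double lam = lambda[l];
    const double l1 = lam * alpha;
    const double denom = 1.0 + lam * (1.0 - alpha);
    int it = 0;
    bool done = false;
    bool full_sweep = true;  // first pass over all features at each lambda
    while (it < max_iter && !done) {
      double max_delta = 0.0;
      for (int j = 0; j < p; ++j) {
        if (!full_sweep && !active[j]) continue;
        double zj;
        if (cov_mode) {
          zj = g[j] + beta[j];  // diag(G) = 1 after standardization
        } else {
          zj = beta[j];
          const double* xj = &X(0, j);
          for (int i = 0; i < n; ++i) zj += v[i] * xj[i] * resid[i];
        }
        double bnew = soft_threshold(zj, l1) / denom;
        double delta = bnew - beta[j];
        if (delta != 0.0) {
          if (cov_mode) {
            const double* Gj = &G[(size_t)j * p];
            for (int k = 0; k < p; ++k) g[k] -= delta * Gj[k];
          } else {
            const double* xj = &X(0, j);
            for (int i = 0; i < n; ++i) resid[i] -= delta * xj[i];
          }
          beta[j] = bnew;
          double ad = std::fabs(delta);
          if (ad > max_delta) max_delta = ad;
        }
        active[j] = beta[j] != 0.0;
      }
      ++it;
      if (max_delta < tol) {
        if (full_sweep) done = true;   // converged on a pass that saw every feature
        else full_sweep = true;        // verify with a full sweep (KKT over inactive set)
      } else {
        full_sweep = false;
      }
    }
    iters[l] = it;
    converged[l] = done;
    for (int j = 0; j < p; ++j) beta_path(j, l) = beta[j];
  }
  return List::create(_["beta"] = beta_path, _["iters"] = iters,
                      _["converged"] = converged);
}
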