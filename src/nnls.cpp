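#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set non-negative least squares:
//   min ||K w - s||_2  subject to w >= 0.
// Deterministic; no RNG. Returns weights and the sum of squared residuals.
// [[Rcpp::export]]
Rcpp::List nnls_cpp(const arma::mat& K, const arma::vec& s,
                    double tol = -1.0, int max_outer = -1) {
  const uword m = K.n_rows, n = K.n_cols;
  if (!K.is_finite() || !s.is_finite())
    Rcpp::stop("non-finite values in NNLS inputs");
  if (s.n_elem != m) Rcpp::stop("dimension mismatch in nnls_cpp");
  if (max_outer < 0) max_outer = 5 * (int)n + 50;
  if (tol < 0) {
    double kmax = K.n_elem ? arma::abs(K).max() : 0.0;
    double smax = s.n_elem ? arma::abs(s).max() : 0.0;
    tol = 10.0 * datum::eps * kmax * smax * (double)std::max(m, n);
    if (tol <= 0) tol = 10.0 * datum::eps;
  }

  vec x(n, fill::zeros);
  std::vector<uword> P;                  // passive (support) set
  std::vector<bool> inP(n, false);
  vec r = s;                             // residual s - K x
  vec grad = K.t() * r;

  int outer = 0;
  while (outer++ < max_outer) {
    // most violated KKT multiplier among active variables
    double wmax = tol; sword t = -1;
    for (uword j = 0; j < n; ++j)
      if (!inP[j] && grad(j) > wmax) { wmax = grad(j); t = (sword)j; }
    if (t < 0) break;
    inP[(uword)t] = true; P.push_back((uword)t);

    int inner_guard = 0;
    while (true) {
      if (++inner_guard > (int)n + 5) break;  // anti-cycling guard
      uvec Pidx(P.size());
      for (size_t k = 0; k < P.size(); ++k) Pidx(k) = P[k];
      mat KP = K.cols(Pidx);
      vec z;
      if (!solve(z, KP, s)) z = pinv(KP) * s;  // least-squares on support
      if (z.min() > 0) {
        x.zeros();
        for (size_t k = 0; k < P.size(); ++k) x(P[k]) = z(k);
        break;
      }
      // step toward z until the first coordinate hits zero
      double alpha = datum::inf;
      for (size_t k = 0; k < P.size(); ++k)
        if (z(k) <= 0) {
          double d = x(P[k]) - z(k);
          double a = (d > 0) ? x(P[k]) / d : 0.0;
          if (a < alpha) alpha = a;
        }
      if (!std::isfinite(alpha)) alpha = 0.0;
      for (size_t k = 0; k < P.size(); ++k)
        x(P[k]) += alpha * (z(k) - x(P[k]));
      // drop zeroed coordinates from the support
      std::vector<uword> Pnew;
      for (size_t k = 0; k < P.size(); ++k) {
        if (x(P[k]) > 0 && z(k) > 0) Pnew.push_back(P[k]);
        else { inP[P[k]] = false; x(P[k]) = 0.0; }
      }
      if (Pnew.size() == P.size()) {  // numerical stall: drop most negative z
        uword drop = 0; double zmin = datum::inf;
        for (size_t k = 0; k < P.size(); ++k)
          if (z(k) < zmin) { zmin = z(k); drop = (uword)k; }
        inP[P[drop]] = false; x(P[drop]) = 0.0;
        Pnew.clear();
        for (size_t k = 0; k < P.size(); ++k)
          if (k != drop) Pnew.push_back(P[k]);
      }
      P.swap(Pnew);
      if (P.empty()) { x.zeros(); break; }
    }
    r = s - K * x;
    grad = K.t() * r;
  }

  return Rcpp::List::create(Rcpp::Named("w") = x,
                            Rcpp::Named("ssr") = dot(r, r));
}
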