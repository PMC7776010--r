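#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Coulomb energy and tangential forces for n unit vectors.
// antipodal > 0 adds mirror-charge interactions aw / |x_i + x_j|: with
// weight 1 the energy is invariant under x_i -> -x_i (half-sphere
// direction schemes); smaller weights merely bias point sets away from
// central symmetry so that the union {+-x_i} covers the sphere of axes.
static double energy_forces(const mat& X, double antipodal, mat& F) {
  const uword n = X.n_rows;
  F.zeros(n, 3);
  double E = 0.0;
  for (uword i = 0; i < n; ++i) {
    for (uword j = i + 1; j < n; ++j) {
      rowvec d = X.row(i) - X.row(j);
      double r2 = dot(d, d);
      if (r2 < 1e-12) r2 = 1e-12;
      double r = std::sqrt(r2);
      E += 1.0 / r;
      rowvec f = d / (r2 * r);
      F.row(i) += f;
      F.row(j) -= f;
      if (antipodal > 0) {
        rowvec dp = X.row(i) + X.row(j);
        double p2 = dot(dp, dp);
        if (p2 < 1e-12) p2 = 1e-12;
        double p = std::sqrt(p2);
        E += antipodal / p;
        rowvec fp = antipodal * dp / (p2 * p);
        F.row(i) += fp;
        F.row(j) += fp;  // force on x_j from -x_i has opposite sign twice
      }
    }
  }
  return E;
}

static void renormalize(mat& X) {
  for (uword i = 0; i < X.n_rows; ++i) {
    double nrm = norm(X.row(i), 2);
    if (nrm < 1e-12) { X(i, 0) = 0; X(i, 1) = 0; X(i, 2) = 1; }
    else X.row(i) /= nrm;
  }
}

// Projected-gradient descent with adaptive step on the repulsion energy.
// Deterministic given the initial configuration.
// [[Rcpp::export]]
arma::mat repulsion_cpp(arma::mat X, double antipodal, int max_iter,
                        double rel_tol) {
  renormalize(X);
  const uword n = X.n_rows;
  mat F(n, 3), Ft(n, 3), M(n, 3, fill::zeros);
  double E = energy_forces(X, antipodal, F);
  // scale-free initial step: fraction of the typical spacing
  double step = 0.1 * std::sqrt(4.0 / (double)n);
  const double beta = 0.9;  // heavy-ball momentum
  for (int it = 0; it < max_iter; ++it) {
    // project forces on tangent planes
    for (uword i = 0; i < n; ++i) {
      rowvec x = X.row(i);
      Ft.row(i) = F.row(i) - dot(F.row(i), x) * x;
    }
    double fmax = 0.0;
    for (uword i = 0; i < n; ++i)
      fmax = std::max(fmax, norm(Ft.row(i), 2));
    if (fmax <= 0) break;
    M = beta * M + (step / fmax) * Ft;
    mat Xnew = X + M;
    renormalize(Xnew);
    mat Fnew(n, 3);
    double Enew = energy_forces(Xnew, antipodal, Fnew);
    if (Enew < E) {
      double dE = (E - Enew) / std::max(E, 1e-300);
      X = Xnew; F = Fnew;
      step *= 1.1;
      E = Enew;
      if (dE < rel_tol && it > 10) break;
    } else {
      M.zeros();           // overshoot: restart momentum, shrink step
      step *= 0.5;
      if (step < 1e-12) break;
    }
    if ((it & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return X;
}
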