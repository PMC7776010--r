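#include <RcppArmadillo.h>
#include <map>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// > 0 when point p lies on the positive side of the oriented plane (a,b,c)
static inline double orient3d(const rowvec& a, const rowvec& b,
                              const rowvec& c, const rowvec& p) {
  rowvec u = b - a, v = c - a, w = p - a;
  return u(0) * (v(1) * w(2) - v(2) * w(1))
       - u(1) * (v(0) * w(2) - v(2) * w(0))
       + u(2) * (v(0) * w(1) - v(1) * w(0));
}

// Anchored gift-wrap pivot around the directed edge (pu -> pv). The anchor
// is the third vertex of the known adjacent face (or a virtual support
// point): every data point lies on the non-negative side of the plane
// (pu, pv, anchor), which makes the dihedral rotation a total order and a
// single scan correct. Returns the index w maximising the rotation; the
// resulting face (pu, pv, w) has all points on its non-positive side.
static sword pivot(const mat& X, const rowvec& pu, const rowvec& pv,
                   const rowvec& anchor, sword skip1, sword skip2) {
  const uword n = X.n_rows;
  sword w = -1;
  rowvec cw = anchor;
  for (uword p = 0; p < n; ++p) {
    if ((sword)p == skip1 || (sword)p == skip2) continue;
    if (orient3d(pu, pv, cw, X.row(p)) > 0) { w = (sword)p; cw = X.row(p); }
  }
  return w;
}

// Gift-wrapping convex hull of points in convex position (unit sphere,
// general position assumed). Returns an f x 3 matrix of 1-based vertex
// indices; triangles oriented outward (counter-clockwise from outside).
// [[Rcpp::export]]
arma::umat convex_hull_cpp(const arma::mat& X) {
  const uword n = X.n_rows;
  if (n < 4) Rcpp::stop("need at least 4 points for a 3D hull");

  // p0: lexicographic minimum (certainly on the hull)
  uword p0 = 0;
  for (uword i = 1; i < n; ++i) {
    if (X(i, 0) < X(p0, 0) ||
        (X(i, 0) == X(p0, 0) && X(i, 1) < X(p0, 1)) ||
        (X(i, 0) == X(p0, 0) && X(i, 1) == X(p0, 1) && X(i, 2) < X(p0, 2)))
      p0 = i;
  }
  // virtual supporting edge through p0 along z; anchor p0 - e_y makes the
  // supporting plane x = x_min the zero of the rotation order
  rowvec e_y = {0, 1, 0}, e_z = {0, 0, 1};
  rowvec P0 = X.row(p0);
  sword q = pivot(X, P0, P0 + e_z, P0 - e_y, (sword)p0, -1);
  if (q < 0) Rcpp::stop("degenerate point set: hull failed");
  // (p0, q) is a hull edge; the plane (p0, p0 + e_z, q) supports the set,
  // so p0 + e_z anchors the pivot for the first real face
  sword r = pivot(X, P0, X.row((uword)q), P0 + e_z, (sword)p0, q);
  if (r < 0) Rcpp::stop("degenerate point set: hull failed");

  struct Task { uword u, v, from; };
  std::vector<uword> faces;
  std::map<std::pair<uword, uword>, bool> seen;  // directed edges done
  std::queue<Task> todo;
  auto push_face = [&](uword a, uword b, uword c) {
    faces.push_back(a); faces.push_back(b); faces.push_back(c);
    const uword vs[3] = {a, b, c};
    for (int k = 0; k < 3; ++k) {
      uword u = vs[k], v = vs[(k + 1) % 3], w = vs[(k + 2) % 3];
      seen[{u, v}] = true;
      if (!seen.count({v, u})) todo.push({v, u, w});
    }
  };
  push_face(p0, (uword)q, (uword)r);

  size_t guard = 0, guard_max = 8 * (size_t)n + 64;
  while (!todo.empty()) {
    if (++guard > guard_max)
      Rcpp::stop("hull did not close (degenerate input?)");
    Task t = todo.front(); todo.pop();
    if (seen.count({t.u, t.v})) continue;  // covered meanwhile
    sword w = pivot(X, X.row(t.u), X.row(t.v), X.row(t.from),
                    (sword)t.u, (sword)t.v);
    if (w < 0) Rcpp::stop("degenerate point set: hull failed");
    push_face(t.u, t.v, (uword)w);
  }

  const uword f = faces.size() / 3;
  umat tri(f, 3);
  for (uword i = 0; i < f; ++i) {
    tri(i, 0) = faces[3 * i] + 1;
    tri(i, 1) = faces[3 * i + 1] + 1;
    tri(i, 2) = faces[3 * i + 2] + 1;
  }
  return tri;
}
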