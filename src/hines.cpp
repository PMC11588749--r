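#include <Rcpp.h>
using namespace Rcpp;

// Parent-vector (Hines) solve of the symmetric tree-tridiagonal system.
// p is 0-based with p[root] = -1; U[i] is the matrix entry coupling node i
// to its parent. Backward sweep eliminates nodes in strictly descending
// index order (valid for any ordering with p[i] < i), forward sweep
// substitutes in ascending order. A forest (several -1 entries) is allowed:
// each root starts its own substitution.

// [[Rcpp::export(name = ".hines_solve_dbl")]]
NumericVector hines_solve_dbl(IntegerVector p, NumericVector D,
                              NumericVector U, NumericVector B) {
  int n = D.size();
  std::vector<double> d(D.begin(), D.end());
  std::vector<double> b(B.begin(), B.end());
  NumericVector V(n);
  for (int i = n - 1; i > 0; --i) {
    int pi = p[i];
    if (pi < 0) continue;
    if (std::fabs(d[i]) < 1e-300) stop("singular system: zero pivot at node %d", i);
    double f = U[i] / d[i];
    d[pi] -= f * U[i];
    b[pi] -= f * b[i];
  }
  for (int i = 0; i < n; ++i) {
    if (std::fabs(d[i]) < 1e-300) stop("singular system: zero pivot at node %d", i);
    if (p[i] < 0) V[i] = b[i] / d[i];
    else          V[i] = (b[i] - U[i] * V[p[i]]) / d[i];
  }
  return V;
}

// Same sweeps with every arithmetic operation rounded to IEEE binary32,
// emulating a 32-bit floating-point hardware datapath.

// [[Rcpp::export(name = ".hines_solve_f32")]]
NumericVector hines_solve_f32(IntegerVector p, NumericVector D,
                              NumericVector U, NumericVector B) {
  int n = D.size();
  std::vector<float> d(n), b(n), u(n);
  for (int i = 0; i < n; ++i) {
    d[i] = (float)D[i]; b[i] = (float)B[i]; u[i] = (float)U[i];
  }
  NumericVector V(n);
  std::vector<float> v(n);
  for (int i = n - 1; i > 0; --i) {
    int pi = p[i];
    if (pi < 0) continue;
    if (std::fabs((double)d[i]) < 1e-30) stop("singular system: zero pivot at node %d", i);
    float f = u[i] / d[i];
    d[pi] -= f * u[i];
    b[pi] -= f * b[i];
  }
  for (int i = 0; i < n; ++i) {
    if (std::fabs((double)d[i]) < 1e-30) stop("singular system: zero pivot at node %d", i);
    if (p[i] < 0) v[i] = b[i] / d[i];
    else          v[i] = (b[i] - u[i] * v[p[i]]) / d[i];
    V[i] = (double)v[i];
  }
  return V;
}
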