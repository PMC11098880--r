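#include <Rcpp.h>
using namespace Rcpp;

// Column-wise max over row groups (symmetric set pooling of PointNet-style
// encoders). Returns the pooled matrix and 1-based argmax rows for backprop.
// [[Rcpp::export]]
List group_max_pool(NumericMatrix x, IntegerVector group, int n_groups) {
  int n = x.nrow(), d = x.ncol();
  NumericMatrix val(n_groups, d);
  IntegerMatrix arg(n_groups, d);
  std::fill(val.begin(), val.end(), R_NegInf);
  for (int j = 0; j < d; ++j) {
    for (int i = 0; i < n; ++i) {
      int g = group[i] - 1;
      double v = x(i, j);
      if (v > val(g, j)) { val(g, j) = v; arg(g, j) = i + 1; }
    }
  }
  // groups with no member pool to zero
  for (int j = 0; j < d; ++j)
    for (int g = 0; g < n_groups; ++g)
      if (arg(g, j) == 0) val(g, j) = 0.0;
  return List::create(_["max"] = val, _["argmax"] = arg);
}

// Backward of group_max_pool: route each pooled gradient entry to the row
// that attained the maximum.
// [[Rcpp::export]]
NumericMatrix group_max_pool_grad(NumericMatrix grad_pooled, IntegerMatrix arg,
                                  int n_rows) {
  int ng = grad_pooled.nrow(), d = grad_pooled.ncol();
  NumericMatrix gx(n_rows, d);
  for (int j = 0; j < d; ++j)
    for (int g = 0; g < ng; ++g) {
      int i = arg(g, j);
      if (i > 0) gx(i - 1, j) += grad_pooled(g, j);
    }
  return gx;
}

// Minimum distance from each point to a set of line segments (skeleton
// bones); used by instance labeling on large clouds.
// [[Rcpp::export]]
NumericVector min_segment_dist(NumericMatrix pts, NumericMatrix a,
                               NumericMatrix b) {
  int n = pts.nrow(), m = a.nrow();
  NumericVector out(n, R_PosInf);
  for (int s = 0; s < m; ++s) {
    double ax = a(s, 0), ay = a(s, 1), az = a(s, 2);
    double dx = b(s, 0) - ax, dy = b(s, 1) - ay, dz = b(s, 2) - az;
    double len2 = dx * dx + dy * dy + dz * dz;
    for (int i = 0; i < n; ++i) {
      double px = pts(i, 0) - ax, py = pts(i, 1) - ay, pz = pts(i, 2) - az;
      double t = len2 > 1e-12 ? (px * dx + py * dy + pz * dz) / len2 : 0.0;
      if (t < 0) t = 0; else if (t > 1) t = 1;
      double ex = px - t * dx, ey = py - t * dy, ez = pz - t * dz;
      double d = std::sqrt(ex * ex + ey * ey + ez * ez);
      if (d < out[i]) out[i] = d;
    }
  }
  return out;
}
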