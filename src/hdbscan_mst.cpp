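#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Core distances and the minimum spanning tree of the mutual reachability
// graph, computed directly from point coordinates (O(n^2) Prim).
// Core distance of point i = distance to its minPts-th nearest neighbour,
// counting the point itself.
// [[Rcpp::export]]
List hdbscan_mst_cpp(NumericMatrix X, int minPts) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> D((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = X(i, c) - X(j, c);
        s += diff * diff;
      }
      double v = std::sqrt(s);
      D[(size_t)i * n + j] = v;
      D[(size_t)j * n + i] = v;
    }
  }
  std::vector<double> core(n);
  std::vector<double> row(n);
  int k = std::min(minPts, n);
  for (int i = 0; i < n; ++i) {
    std::copy(D.begin() + (size_t)i * n, D.begin() + (size_t)(i + 1) * n,
              row.begin());
    std::nth_element(row.begin(), row.begin() + (k - 1), row.end());
    core[i] = row[k - 1];
  }
  // Prim on mutual reachability max(core_i, core_j, d_ij)
  std::vector<bool> in_tree(n, false);
  std::vector<double> best_w(n, R_PosInf);
  std::vector<int> best_from(n, -1);
  IntegerVector from(n - 1), to(n - 1);
  NumericVector w(n - 1);
  int v = 0;
  in_tree[0] = true;
  for (int step = 0; step < n - 1; ++step) {
    const double cv = core[v];
    const double *drow = &D[(size_t)v * n];
    for (int u = 0; u < n; ++u) {
      if (in_tree[u]) continue;
      double m = drow[u];
      if (core[u] > m) m = core[u];
      if (cv > m) m = cv;
      if (m < best_w[u]) {
        best_w[u] = m;
        best_from[u] = v;
      }
    }
    int u_min = -1;
    double w_min = R_PosInf;
    for (int u = 0; u < n; ++u) {
      if (!in_tree[u] && best_w[u] < w_min) {
        w_min = best_w[u];
        u_min = u;
      }
    }
    from[step] = best_from[u_min] + 1;
    to[step] = u_min + 1;
    w[step] = w_min;
    in_tree[u_min] = true;
    v = u_min;
  }
  return List::create(Named("from") = from, Named("to") = to, Named("w") = w,
                      Named("core") = NumericVector(core.begin(), core.end()));
}
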