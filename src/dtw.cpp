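#include <Rcpp.h>
using namespace Rcpp;

// Local distance between two scaled values.
// dist: 0 = absolute difference, 1 = squared difference.
static inline double local_d(double x, double y, int dist) {
  double v = x - y;
  return dist == 0 ? std::fabs(v) : v * v;
}

// Accumulated-cost DTW.
// step: 0 = "fewer_delays" (unweighted min recursion, symmetric1-like),
//       1 = "symmetric_weighted" (diagonal step counts the local cost twice,
//           symmetric2-like).  D(0,0) = d(0,0) for both.
// Returns only the distance; traceback handled by dtw_path_impl.
static void fill_cost(const NumericVector& a, const NumericVector& b,
                      int step, int dist, std::vector<double>& D) {
  const int n = a.size(), m = b.size();
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double d = local_d(a[i], b[j], dist);
      double acc;
      if (i == 0 && j == 0) {
        acc = d;
      } else {
        double best = R_PosInf;
        if (i > 0 && j > 0) {
          double diag = D[(i - 1) * m + (j - 1)] + (step == 1 ? 2.0 * d : d);
          if (diag < best) best = diag;
        }
        if (i > 0) {
          double up = D[(i - 1) * m + j] + d;
          if (up < best) best = up;
        }
        if (j > 0) {
          double left = D[i * m + (j - 1)] + d;
          if (left < best) best = left;
        }
        acc = best;
      }
      D[i * m + j] = acc;
    }
  }
}

// [[Rcpp::export]]
double cpp_dtw_distance(NumericVector a, NumericVector b, int step, int dist) {
  const int n = a.size(), m = b.size();
  std::vector<double> D((size_t)n * m);
  fill_cost(a, b, step, dist, D);
  return D[(size_t)n * m - 1];
}

// Distance plus one optimal warp path (1-based index pairs).
// Traceback tie-break: prefer the diagonal predecessor, then (i-1, j),
// then (i, j-1), so paths are reproducible.
// [[Rcpp::export]]
List cpp_dtw(NumericVector a, NumericVector b, int step, int dist) {
  const int n = a.size(), m = b.size();
  std::vector<double> D((size_t)n * m);
  fill_cost(a, b, step, dist, D);

  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i + 1); pj.push_back(j + 1);
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    double d = local_d(a[i], b[j], dist);
    double acc = D[(size_t)i * m + j];
    if (i > 0 && j > 0 &&
        std::fabs(D[(size_t)(i - 1) * m + (j - 1)] +
                  (step == 1 ? 2.0 * d : d) - acc) <=
          eps * (1.0 + std::fabs(acc))) {
      --i; --j;
    } else if (i > 0 &&
               std::fabs(D[(size_t)(i - 1) * m + j] + d - acc) <=
                 eps * (1.0 + std::fabs(acc))) {
      --i;
    } else {
      --j;
    }
    pi.push_back(i + 1); pj.push_back(j + 1);
  }
  const int L = pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {           // reverse into start-to-end order
    path(k, 0) = pi[L - 1 - k];
    path(k, 1) = pj[L - 1 - k];
  }
  return List::create(_["distance"] = D[(size_t)n * m - 1], _["path"] = path);
}

// Null distances for a batch of joint permutations.  perm_a is B x length(a),
// perm_b is B x length(b); row k holds the 1-based order applied to each
// series in draw k.
// [[Rcpp::export]]
NumericVector cpp_dtw_null(NumericVector a, NumericVector b,
                           IntegerMatrix perm_a, IntegerMatrix perm_b,
                           int step, int dist) {
  const int B = perm_a.nrow();
  const int n = a.size(), m = b.size();
  NumericVector out(B);
  NumericVector pa(n), pb(m);
  std::vector<double> D((size_t)n * m);
  for (int k = 0; k < B; ++k) {
    for (int i = 0; i < n; ++i) pa[i] = a[perm_a(k, i) - 1];
    for (int j = 0; j < m; ++j) pb[j] = b[perm_b(k, j) - 1];
    fill_cost(pa, pb, step, dist, D);
    out[k] = D[(size_t)n * m - 1];
  }
  return out;
}
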