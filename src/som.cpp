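// Online SOM training kernel and best-matching-unit search.
//
// The training loop mirrors the classic kohonen-derived C kernel used for
// cytometry SOMs: a bubble (step) neighbourhood in which every node whose
// squared grid distance to the BMU is <= radius(t) receives the full
// learning-rate update, with alpha and radius decaying linearly over the
// rlen * n presentation steps. The presentation order is drawn in R (so the
// RNG is R's seeded Mersenne-Twister) and passed in as a 0-based index
// vector; results are therefore reproducible across platforms and
// independent of thread count (the kernel is single-threaded by design).

#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

enum Metric { MANHATTAN = 0, EUCLIDEAN = 1, CHEBYSHEV = 2, COSINE = 3 };

static inline double row_distance(const double* x, const double* y,
                                  int d, int metric) {
  switch (metric) {
  case MANHATTAN: {
    double s = 0.0;
    for (int c = 0; c < d; ++c) s += std::fabs(x[c] - y[c]);
    return s;
  }
  case EUCLIDEAN: {
    double s = 0.0;
    for (int c = 0; c < d; ++c) { double t = x[c] - y[c]; s += t * t; }
    return std::sqrt(s);
  }
  case CHEBYSHEV: {
    double s = 0.0;
    for (int c = 0; c < d; ++c) {
      double t = std::fabs(x[c] - y[c]);
      if (t > s) s = t;
    }
    return s;
  }
  case COSINE: {
    // 1 - cosine similarity; a zero vector is assigned similarity 0 so the
    // distance stays defined (no NaN).
    double dot = 0.0, nx = 0.0, ny = 0.0;
    for (int c = 0; c < d; ++c) {
      dot += x[c] * y[c];
      nx += x[c] * x[c];
      ny += y[c] * y[c];
    }
    double sim = (nx > 0.0 && ny > 0.0) ? dot / std::sqrt(nx * ny) : 0.0;
    return 1.0 - sim;
  }
  }
  return NA_REAL; // unreachable
}

// Copy row i of a column-major n x d matrix into a contiguous buffer.
static inline void get_row(const NumericMatrix& M, int i, std::vector<double>& buf) {
  const int d = M.ncol(), n = M.nrow();
  for (int c = 0; c < d; ++c) buf[c] = M[(std::size_t)c * n + i];
}

// [[Rcpp::export(name = ".cpp_train_som")]]
NumericMatrix cpp_train_som(NumericMatrix X, NumericMatrix codes,
                            NumericMatrix nhbrdist,
                            double alpha_start, double alpha_end,
                            double radius_start, double radius_end,
                            IntegerVector order, int metric) {
  const int n = X.nrow(), d = X.ncol(), m = codes.nrow();
  if (codes.ncol() != d) stop("codes and data disagree on dimensionality");
  if (nhbrdist.nrow() != m || nhbrdist.ncol() != m)
    stop("nhbrdist must be n_nodes x n_nodes");

  NumericMatrix out = clone(codes);
  const R_xlen_t T = order.size();
  std::vector<double> x(d), code(d);

  for (R_xlen_t t = 0; t < T; ++t) {
    const int i = order[t];
    if (i < 0 || i >= n) stop("presentation index out of range");
    get_row(X, i, x);

    // best matching unit; ties broken by lowest node index
    int bmu = 0;
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < m; ++j) {
      get_row(out, j, code);
      double dist = row_distance(x.data(), code.data(), d, metric);
      if (dist < best) { best = dist; bmu = j; }
    }

    const double frac = (double)t / (double)T;
    const double alpha = alpha_start - (alpha_start - alpha_end) * frac;
    double radius = radius_start - (radius_start - radius_end) * frac;
    if (radius < 1.0) radius = 0.5; // only the BMU itself updates

    for (int j = 0; j < m; ++j) {
      if (nhbrdist[(std::size_t)bmu * m + j] <= radius) {
        for (int c = 0; c < d; ++c) {
          const std::size_t idx = (std::size_t)c * m + j;
          out[idx] += alpha * (x[c] - out[idx]);
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_assign_bmu")]]
List cpp_assign_bmu(NumericMatrix X, NumericMatrix codes, int metric) {
  const int n = X.nrow(), d = X.ncol(), m = codes.nrow();
  if (codes.ncol() != d) stop("codes and data disagree on dimensionality");
  IntegerVector cluster(n);
  NumericVector distance(n);
  std::vector<double> x(d), code(d);
  for (int i = 0; i < n; ++i) {
    get_row(X, i, x);
    int bmu = 0;
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < m; ++j) {
      get_row(codes, j, code);
      double dist = row_distance(x.data(), code.data(), d, metric);
      if (dist < best) { best = dist; bmu = j; }
    }
    cluster[i] = bmu + 1; // 1-based node labels on the R side
    distance[i] = best;
  }
  return List::create(_["cluster_id"] = cluster, _["distance"] = distance);
}
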