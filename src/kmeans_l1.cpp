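#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <limits>

using namespace Rcpp;

// Coordinate-wise median of the points (columns of xt) listed in idx.
// Even counts average the two middle order statistics.
static void update_median(const std::vector<double>& xt, int d,
                          const std::vector<int>& idx,
                          std::vector<double>& centroid, int coff) {
  const int m = (int)idx.size();
  std::vector<double> col(m);
  for (int j = 0; j < d; ++j) {
    for (int i = 0; i < m; ++i) col[i] = xt[(size_t)idx[i] * d + j];
    const int mid = m / 2;
    std::nth_element(col.begin(), col.begin() + mid, col.end());
    double v = col[mid];
    if (m % 2 == 0) {
      double lo = *std::max_element(col.begin(), col.begin() + mid);
      v = 0.5 * (lo + v);
    }
    centroid[(size_t)coff * d + j] = v;
  }
}

// L1 distance with early abandonment once the partial sum exceeds bound.
static inline double l1_dist_bounded(const double* a, const double* b,
                                     int d, double bound) {
  double s = 0.0;
  int j = 0;
  for (; j + 4 <= d; j += 4) {
    s += std::fabs(a[j] - b[j]) + std::fabs(a[j + 1] - b[j + 1]) +
         std::fabs(a[j + 2] - b[j + 2]) + std::fabs(a[j + 3] - b[j + 3]);
    if (s >= bound) return s;
  }
  for (; j < d; ++j) s += std::fabs(a[j] - b[j]);
  return s;
}

// L1 (cityblock) K-means: minimum-distance assignment, coordinate-wise
// median centroid update, iterated to label convergence; best restart by
// total cost. init_idx is n_init x k of 1-based row indices for the
// initial centroids of each restart.
// [[Rcpp::export]]
List kmeans_l1_cpp(NumericMatrix x, int k, IntegerMatrix init_idx,
                   int max_iter) {
  const int n = x.nrow(), d = x.ncol();
  const int n_init = init_idx.nrow();

  // points stored contiguously (row i of x at xt[i*d .. i*d+d-1])
  std::vector<double> xt((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) xt[(size_t)i * d + j] = x(i, j);

  IntegerVector best_labels(n);
  std::vector<double> best_cen((size_t)k * d);
  double best_cost = std::numeric_limits<double>::infinity();
  int best_iter = 0, best_init = -1, total_reseeds = 0;
  std::vector<double> best_trace;

  std::vector<double> cen((size_t)k * d);
  std::vector<int> labels(n), prev(n);
  std::vector<double> mind(n);

  for (int ini = 0; ini < n_init; ++ini) {
    for (int c = 0; c < k; ++c) {
      int r = init_idx(ini, c) - 1;
      std::copy(xt.begin() + (size_t)r * d, xt.begin() + (size_t)(r + 1) * d,
                cen.begin() + (size_t)c * d);
    }
    std::fill(prev.begin(), prev.end(), -1);
    std::vector<double> trace;
    double cost = 0.0;
    int it = 0, reseeds = 0;

    for (it = 0; it < max_iter; ++it) {
      // assignment step (ties -> lowest cluster index)
      cost = 0.0;
      for (int i = 0; i < n; ++i) {
        const double* pi = &xt[(size_t)i * d];
        double dm = l1_dist_bounded(pi, &cen[0], d,
                                    std::numeric_limits<double>::infinity());
        int am = 0;
        for (int c = 1; c < k; ++c) {
          double dc = l1_dist_bounded(pi, &cen[(size_t)c * d], d, dm);
          if (dc < dm) { dm = dc; am = c; }
        }
        labels[i] = am;
        mind[i] = dm;
        cost += dm;
      }
      trace.push_back(cost);
      if (labels == prev) break;
      prev = labels;

      // update step, with empty-cluster reseeding from the farthest point
      std::vector< std::vector<int> > members(k);
      for (int i = 0; i < n; ++i) members[labels[i]].push_back(i);
      for (int c = 0; c < k; ++c) {
        if (members[c].empty()) {
          int far = 0; double fd = -1.0;
          for (int i = 0; i < n; ++i)
            if (mind[i] > fd) { fd = mind[i]; far = i; }
          std::copy(xt.begin() + (size_t)far * d,
                    xt.begin() + (size_t)(far + 1) * d,
                    cen.begin() + (size_t)c * d);
          mind[far] = 0.0;
          ++reseeds;
        } else {
          update_median(xt, d, members[c], cen, c);
        }
      }
    }

    total_reseeds += reseeds;
    if (cost < best_cost) {
      best_cost = cost;
      for (int i = 0; i < n; ++i) best_labels[i] = labels[i] + 1;
      best_cen = cen;
      best_iter = it + 1;
      best_init = ini + 1;
      best_trace = trace;
    }
  }

  NumericMatrix cen_out(k, d);
  for (int c = 0; c < k; ++c)
    for (int j = 0; j < d; ++j) cen_out(c, j) = best_cen[(size_t)c * d + j];

  return List::create(
    _["labels"] = best_labels,
    _["centroids"] = cen_out,
    _["cost"] = best_cost,
    _["iterations"] = best_iter,
    _["best_init"] = best_init,
    _["n_reseeds"] = total_reseeds,
    _["cost_trace"] = NumericVector(best_trace.begin(), best_trace.end()));
}
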