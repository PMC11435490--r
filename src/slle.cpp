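#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact nearest-neighbour search with a temporal (Theiler) exclusion
// window. X is the delay-embedded trajectory (rows = points). Returns the
// 1-based index of each point's nearest neighbour among points with
// |i - j| > theiler, and the Euclidean distance.
// [[Rcpp::export(name = ".nn_search_cpp")]]
List nn_search_cpp(NumericMatrix X, int theiler) {
  const int n = X.nrow(), m = X.ncol();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bj = -1;
    for (int j = 0; j < n; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        const double d = X(i, k) - X(j, k);
        d2 += d * d;
        if (d2 >= best) break;
      }
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = (bj >= 0) ? std::sqrt(best) : NA_REAL;
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// False-nearest-neighbour fractions for embedding dimensions 1..max_dim.
// For dimension m the neighbour of each point is found in the m-dim
// embedding (self excluded, minimum temporal separation min_sep); the
// neighbour is false if the extra (m+1)-th coordinate stretches the
// distance by more than rtol, or if the (m+1)-dim distance exceeds
// atol * attractor size (sd of the series).
// [[Rcpp::export(name = ".fnn_fractions_cpp")]]
NumericVector fnn_fractions_cpp(NumericVector x, int tau, int max_dim,
                                double rtol, double atol, int min_sep,
                                double stop_below = -1.0) {
  const int n = x.size();
  // attractor size
  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += x[i];
  mu /= n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (x[i] - mu) * (x[i] - mu);
  const double ra = std::sqrt(ss / (n - 1));
  NumericVector frac(max_dim, NA_REAL);
  for (int m = 1; m <= max_dim; ++m) {
    const int np = n - m * tau;  // need the (m+1)-th coordinate too
    if (np < 10) break;
    int n_false = 0, n_tot = 0;
    for (int i = 0; i < np; ++i) {
      double best = std::numeric_limits<double>::infinity();
      int bj = -1;
      for (int j = 0; j < np; ++j) {
        if (std::abs(i - j) <= min_sep) continue;
        double d2 = 0.0;
        for (int k = 0; k < m; ++k) {
          const double d = x[i + k * tau] - x[j + k * tau];
          d2 += d * d;
          if (d2 >= best) break;
        }
        if (d2 < best) { best = d2; bj = j; }
      }
      if (bj < 0) continue;
      const double dm = std::sqrt(best);
      const double extra = std::abs(x[i + m * tau] - x[bj + m * tau]);
      const double dm1 = std::sqrt(best + extra * extra);
      bool is_false = false;
      if (dm > 0) {
        if (extra / dm > rtol) is_false = true;
      } else if (extra > 0) {
        is_false = true;
      }
      if (dm1 / ra > atol) is_false = true;
      ++n_tot;
      if (is_false) ++n_false;
    }
    frac[m - 1] = n_tot > 0 ? (double)n_false / n_tot : NA_REAL;
    if (stop_below >= 0 && n_tot > 0 && frac[m - 1] < stop_below) break;
  }
  return frac;
}

// Mean log divergence of initially nearest trajectory pairs, offsets
// 0..max_offset. Pairs are the Theiler-excluded nearest neighbours; at
// each offset only pairs with both indices in range and separation above
// a numerical floor contribute (d_floor screens out duplicate points
// that differ only by rounding noise).
// [[Rcpp::export(name = ".divergence_curve_cpp")]]
NumericVector divergence_curve_cpp(NumericMatrix X, IntegerVector nn_idx,
                                   int max_offset, double d_floor) {
  const int n = X.nrow(), m = X.ncol();
  NumericVector out(max_offset + 1, NA_REAL);
  for (int k = 0; k <= max_offset; ++k) {
    double acc = 0.0;
    int cnt = 0;
    for (int i = 0; i < n; ++i) {
      const int j = nn_idx[i] - 1;
      if (j < 0) continue;
      if (i + k >= n || j + k >= n) continue;
      double d2 = 0.0;
      for (int c = 0; c < m; ++c) {
        const double d = X(i + k, c) - X(j + k, c);
        d2 += d * d;
      }
      if (d2 > d_floor * d_floor) { acc += 0.5 * std::log(d2); ++cnt; }
    }
    if (cnt > 0) out[k] = acc / cnt;
  }
  return out;
}
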