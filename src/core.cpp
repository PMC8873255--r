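#include <Rcpp.h>
using namespace Rcpp;

// Greedy left-to-right return-loop scan within a single recording bout.
// x, y: planar coordinates (m); t: time (s); cum: cumulative path length (m)
// with cum[0] = 0.  Returns a 2-column matrix of 1-based (start, end) sample
// indices.  At each candidate start i the admissible endpoints are the j > i
// with endpoint distance <= slack, duration within [min_dur, max_dur] and
// path length >= min_len; the segment with maximum path length (ties: larger
// j) is emitted and the scan resumes after its end.
// [[Rcpp::export]]
IntegerMatrix greedy_segments_cpp(NumericVector x, NumericVector y,
                                  NumericVector t, NumericVector cum,
                                  double slack, double min_dur,
                                  double max_dur, double min_len) {
  int n = x.size();
  std::vector<int> starts, ends;
  double slack2 = slack * slack;
  int i = 0;
  while (i < n - 1) {
    int best = -1;
    double best_len = -1.0;
    for (int j = i + 1; j < n; ++j) {
      double dur = t[j] - t[i];
      if (dur > max_dur) break;
      if (dur < min_dur) continue;
      double dx = x[j] - x[i], dy = y[j] - y[i];
      if (dx * dx + dy * dy > slack2) continue;
      double len = cum[j] - cum[i];
      if (len < min_len) continue;
      if (len >= best_len) {  // >= picks the larger j on ties
        best_len = len;
        best = j;
      }
    }
    if (best >= 0) {
      starts.push_back(i + 1);
      ends.push_back(best + 1);
      i = best + 1;
    } else {
      ++i;
    }
  }
  IntegerMatrix out(starts.size(), 2);
  for (size_t k = 0; k < starts.size(); ++k) {
    out(k, 0) = starts[k];
    out(k, 1) = ends[k];
  }
  return out;
}

// Plain logistic-loss stochastic gradient descent with a fixed step budget.
// X: n x p design (intercept column included by the caller); yv: 0/1 labels;
// w0: initial weights; order: 1-based row index visited at each step
// (generated by the caller's RNG so the fit is reproducible); lr: constant
// learning rate.  No regularisation.
// [[Rcpp::export]]
NumericVector sgd_logistic_cpp(NumericMatrix X, NumericVector yv,
                               NumericVector w0, IntegerVector order,
                               double lr) {
  int p = X.ncol();
  NumericVector w = clone(w0);
  int steps = order.size();
  for (int s = 0; s < steps; ++s) {
    int i = order[s] - 1;
    double z = 0.0;
    for (int k = 0; k < p; ++k) z += w[k] * X(i, k);
    double pr = 1.0 / (1.0 + std::exp(-z));
    double g = pr - yv[i];
    for (int k = 0; k < p; ++k) w[k] -= lr * g * X(i, k);
  }
  return w;
}
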