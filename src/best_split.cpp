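#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

static double entropy_from_counts(const std::vector<double>& cnt, double n) {
  if (n <= 0.0) return 0.0;
  double h = 0.0;
  for (double c : cnt) {
    if (c > 0.0) {
      double p = c / n;
      h -= p * std::log(p);
    }
  }
  return h;
}

// Best (feature, threshold) split by information gain on the class variable.
// Candidate thresholds are midpoints between consecutive distinct sorted
// values of each feature. Ties in gain are broken toward the lower feature
// index and the lower threshold (features and cut positions are scanned in
// ascending order and only a strictly better gain replaces the incumbent).
// y is 1-based class indexing; returns feature = -1 if no candidate exists.
// [[Rcpp::export(name = ".best_split_cpp")]]
List best_split_cpp(NumericMatrix X, IntegerVector y, int n_classes) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> total(n_classes, 0.0);
  for (int i = 0; i < n; ++i) total[y[i] - 1] += 1.0;
  const double h_parent = entropy_from_counts(total, (double)n);

  double best_gain = 0.0, best_thr = NA_REAL;
  int best_feat = -1;
  const double eps = 1e-12;

  std::vector<int> ord(n);
  std::vector<double> left(n_classes), right(n_classes);

  for (int j = 0; j < p; ++j) {
    NumericMatrix::Column xj = X(_, j);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return xj[a] < xj[b]; });
    std::fill(left.begin(), left.end(), 0.0);
    for (int c = 0; c < n_classes; ++c) right[c] = total[c];

    for (int i = 0; i < n - 1; ++i) {
      const int cls = y[ord[i]] - 1;
      left[cls] += 1.0;
      right[cls] -= 1.0;
      const double xv = xj[ord[i]], xn = xj[ord[i + 1]];
      if (xn <= xv) continue; // not a boundary between distinct values
      const double nl = (double)(i + 1), nr = (double)(n - i - 1);
      const double gain = h_parent -
        (nl / n) * entropy_from_counts(left, nl) -
        (nr / n) * entropy_from_counts(right, nr);
      if (gain > best_gain + eps) {
        best_gain = gain;
        best_feat = j + 1;
        best_thr = 0.5 * (xv + xn);
      }
    }
  }
  return List::create(
    _["feature"] = best_feat,
    _["threshold"] = best_thr,
    _["gain"] = best_gain
  );
}
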