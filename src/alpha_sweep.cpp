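// Exact minimization of the backbone objective over the retention
// threshold. The objective J(alpha) = mean_w |C_{w+1}(alpha) - C_w(alpha)|
// is piecewise constant in alpha with breakpoints at the edges' retention
// scores, so a single ascending sweep over the breakpoints visits every
// attainable value of J.
#include <Rcpp.h>
#include <algorithm>
#include <numeric>

// edge i: retention score s[i], window index w[i] (0-based), weight wt[i].
// Only edges with s >= a0 are retained anywhere in [a0, a1].
// [[Rcpp::export]]
Rcpp::List cpp_alpha_sweep(const Rcpp::NumericVector& s,
                           const Rcpp::IntegerVector& w,
                           const Rcpp::NumericVector& wt,
                           int n_windows, double a0, double a1) {
  const int m = s.size();
  std::vector<double> sum(n_windows, 0.0);
  std::vector<int> cnt(n_windows, 0);
  std::vector<int> idx;
  idx.reserve(m);
  for (int i = 0; i < m; ++i) {
    if (s[i] >= a0) { sum[w[i]] += wt[i]; cnt[w[i]] += 1; }
  }
  auto C = [&](int j) { return cnt[j] > 0 ? sum[j] / cnt[j] : 0.0; };
  double D = 0.0;
  for (int j = 0; j + 1 < n_windows; ++j) D += std::fabs(C(j + 1) - C(j));
  const double denom = n_windows - 1;
  double best_J = D / denom, best_alpha = a0;

  // removal events: edges whose score lies inside [a0, a1]
  for (int i = 0; i < m; ++i)
    if (s[i] >= a0 && s[i] <= a1) idx.push_back(i);
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return s[a] < s[b]; });

  size_t i = 0;
  while (i < idx.size()) {
    double cur = s[idx[i]];
    // drop every edge scoring exactly cur, updating the adjacent
    // consecutive-window differences incrementally
    while (i < idx.size() && s[idx[i]] == cur) {
      int e = idx[i];
      int j = w[e];
      if (j > 0) D -= std::fabs(C(j) - C(j - 1));
      if (j + 1 < n_windows) D -= std::fabs(C(j + 1) - C(j));
      sum[j] -= wt[e]; cnt[j] -= 1;
      if (cnt[j] == 0) sum[j] = 0.0;
      if (j > 0) D += std::fabs(C(j) - C(j - 1));
      if (j + 1 < n_windows) D += std::fabs(C(j + 1) - C(j));
      ++i;
    }
    // the new retained set holds for alpha in (cur, next_s]
    double rep = (i < idx.size()) ? s[idx[i]] : a1;
    if (rep > a1) rep = a1;
    double J = D / denom;
    if (J < best_J - 1e-15) { best_J = J; best_alpha = rep; }
  }
  return Rcpp::List::create(Rcpp::Named("alpha") = best_alpha,
                            Rcpp::Named("J") = best_J);
}
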