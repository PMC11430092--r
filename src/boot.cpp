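// Bootstrap median of medians. Uses R's RNG stream (seeded from R) and
// nth_element selection rather than full sorts.
#include <Rcpp.h>
#include <algorithm>

// [[Rcpp::export]]
double cpp_boot_median(const Rcpp::NumericVector& pool, int n_iter) {
  const int n = pool.size();
  std::vector<double> buf(n), meds(n_iter);
  Rcpp::RNGScope scope;
  for (int i = 0; i < n_iter; ++i) {
    for (int j = 0; j < n; ++j)
      buf[j] = pool[(int)(R::unif_rand() * n)];
    const int h = n / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double m = buf[h];
    if (n % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + h);
      m = (m + lo) / 2.0;
    }
    meds[i] = m;
  }
  const int h = n_iter / 2;
  std::nth_element(meds.begin(), meds.begin() + h, meds.end());
  double m = meds[h];
  if (n_iter % 2 == 0) {
    double lo = *std::max_element(meds.begin(), meds.begin() + h);
    m = (m + lo) / 2.0;
  }
  return m;
}
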