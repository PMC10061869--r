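#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// median by selection; scrambles v
static double median_inplace(std::vector<double> &v) {
  const size_t n = v.size();
  const size_t mid = n / 2;
  std::nth_element(v.begin(), v.begin() + mid, v.end());
  double m = v[mid];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + mid);
    m = 0.5 * (m + lo);
  }
  return m;
}

static double mad_inplace(std::vector<double> &v, double constant) {
  const double med = median_inplace(v);
  for (size_t i = 0; i < v.size(); ++i) v[i] = std::fabs(v[i] - med);
  return constant * median_inplace(v);
}

//' @describeIn bootstrap_mad C++ inner loop; resamples with R's RNG, so the
//'   surrounding [set.seed()] determines the result.
//' @keywords internal
// [[Rcpp::export]]
double cpp_bootstrap_mad(NumericVector x, int B, double constant) {
  const int n = x.size();
  if (n < 2) stop("need at least 2 values");
  if (B < 1) stop("B must be >= 1");
  std::vector<double> mads((size_t)B);
  std::vector<double> samp((size_t)n);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) {
      int j = (int)(unif_rand() * n);
      if (j == n) j = n - 1;  // unif_rand() is in [0, 1)
      samp[(size_t)i] = x[j];
    }
    mads[(size_t)b] = mad_inplace(samp, constant);
  }
  return median_inplace(mads);
}
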