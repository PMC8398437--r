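#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Exact two-sided permutation p-value for Kendall's tau-b.
// Enumerates every distinct ordering of y (std::next_permutation over the
// sorted values; tied values collapse arrangements that share S, which keeps
// the count proportional to the full n! enumeration) and counts orderings
// whose |S| = |C - D| reaches the observed one. The tie structure of both
// margins is permutation-invariant, so comparing S is equivalent to
// comparing |tau_b|.
// [[Rcpp::export]]
double tau_exact_perm_p(Rcpp::NumericVector x, Rcpp::NumericVector y) {
  const int n = x.size();
  if (y.size() != n) Rcpp::stop("x and y must have equal length");
  if (n < 2) Rcpp::stop("need at least 2 observations");
  if (n > 11) Rcpp::stop("exact enumeration limited to n <= 11");

  std::vector<int> sx(n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double d = x[j] - x[i];
      sx[i * n + j] = (d > 0) - (d < 0);
    }

  auto stat = [&](const std::vector<double>& yy) {
    long s = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double d = yy[j] - yy[i];
        s += sx[i * n + j] * ((d > 0) - (d < 0));
      }
    return s;
  };

  std::vector<double> y0(y.begin(), y.end());
  long s_obs = std::labs(stat(y0));

  std::vector<double> yp(y0);
  std::sort(yp.begin(), yp.end());
  double hits = 0, total = 0;
  do {
    ++total;
    if (std::labs(stat(yp)) >= s_obs) ++hits;
  } while (std::next_permutation(yp.begin(), yp.end()));
  return hits / total;
}
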