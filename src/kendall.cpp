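// Exact permutation null for Kendall's tau-b: enumerate all n! orderings of
// y against fixed x and count how many give |S| (concordant - discordant)
// at least as extreme as observed. Feasible for n <= 10.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

long long s_stat(const std::vector<double>& x, const std::vector<double>& y) {
  long long s = 0;
  const int n = (int)x.size();
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i];
      double p = dx * dy;
      if (p > 0) ++s;
      else if (p < 0) --s;
    }
  return s;
}

} // namespace

// [[Rcpp::export]]
double kendall_exact_p_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n > 10) stop("exact enumeration limited to n <= 10");
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> yv(y.begin(), y.end());
  long long obs = std::llabs(s_stat(xv, yv));

  std::vector<double> perm(yv);
  std::sort(perm.begin(), perm.end());
  long long hits = 0, total = 0;
  do {
    ++total;
    if (std::llabs(s_stat(xv, perm)) >= obs) ++hits;
  } while (std::next_permutation(perm.begin(), perm.end()));
  // next_permutation over a multiset enumerates distinct orderings only;
  // each distinct ordering has equal multiplicity under random permutation,
  // so the proportion is the exact two-sided p-value.
  return (double)hits / (double)total;
}
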