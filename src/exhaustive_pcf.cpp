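#include <Rcpp.h>
using namespace Rcpp;

// Brute-force reference for the penalized least-squares changepoint fit:
// enumerate all 2^(n-1) breakpoint subsets and keep the cheapest. Used only
// to validate the dynamic program; n is capped by the R wrapper.
// [[Rcpp::export]]
List exhaustive_pcf_cpp(NumericVector y, double gamma) {
  const int n = y.size();
  if (n == 0) return List::create(_["cost"] = 0.0,
                                  _["breakpoints"] = IntegerVector(0));
  // sse[i][j]: residual sum of squares of y[i..j]
  std::vector<std::vector<double>> sse(n, std::vector<double>(n, 0.0));
  for (int i = 0; i < n; ++i) {
    double s = 0.0, s2 = 0.0;
    for (int j = i; j < n; ++j) {
      s += y[j];
      s2 += y[j] * y[j];
      const int len = j - i + 1;
      sse[i][j] = s2 - s * s / len;
    }
  }
  const unsigned long nsub = 1UL << (n - 1);
  double best = R_PosInf;
  unsigned long best_mask = 0;
  for (unsigned long mask = 0; mask < nsub; ++mask) {
    double cost = 0.0;
    int start = 0, k = 0;
    for (int i = 0; i < n - 1; ++i) {
      if (mask & (1UL << i)) {
        cost += sse[start][i] + gamma;
        start = i + 1;
        ++k;
      }
      if (cost >= best) break;
    }
    if (cost >= best) continue;
    cost += sse[start][n - 1];
    if (cost < best) {
      best = cost;
      best_mask = mask;
    }
  }
  std::vector<int> bk;
  for (int i = 0; i < n - 1; ++i)
    if (best_mask & (1UL << i)) bk.push_back(i + 1);  // 1-based index of last
  return List::create(_["cost"] = best,
                      _["breakpoints"] = wrap(bk));
}
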