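#include <Rcpp.h>
using namespace Rcpp;

// Mean template-match frequency B^m(r) with Chebyshev distance and
// self-matches excluded. Templates X_i = (x_i, ..., x_{i+m-1}),
// i = 1..N-m+1; each B_i averages over the other N-m templates and
// B^m averages the B_i. Theta(0) counts as a match (d <= r).
static double match_mean(const NumericVector& x, int m, double r) {
  int n = x.size();
  int nt = n - m + 1;          // number of templates
  if (nt < 2) return NA_REAL;
  std::vector<double> hits(nt, 0.0);
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(x[i + k] - x[j + k]);
        if (a > d) d = a;
        if (d > r) break;
      }
      if (d <= r) { hits[i] += 1.0; hits[j] += 1.0; }
    }
  }
  double s = 0.0;
  for (int i = 0; i < nt; ++i) s += hits[i] / (nt - 1);
  return s / nt;
}

// [[Rcpp::export]]
NumericVector sampen_match_means(NumericVector x, int m, double r) {
  NumericVector out(2);
  out[0] = match_mean(x, m, r);      // B^m
  out[1] = match_mean(x, m + 1, r);  // B^{m+1}
  return out;
}
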