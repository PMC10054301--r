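#include <Rcpp.h>
using namespace Rcpp;

// Match counts for the phi statistic of approximate entropy.
//
// For each of the M = N - m + 1 template vectors v_i = (x_i, ..., x_{i+m-1})
// counts the vectors v_j (j = 1..M, including j = i) whose distance from v_i
// is <= r. The match rule is inclusive: distance exactly r counts.
//
// For the Euclidean norm the comparison is done on the squared distance
// against r^2, never through sqrt, so a pair constructed at exactly distance
// r is counted without rounding surprises.
//
// [[Rcpp::export(name = ".phi_match_counts_cpp")]]
IntegerVector phi_match_counts_cpp(NumericVector x, int m, double r,
                                   bool chebyshev) {
  const int N = x.size();
  const int M = N - m + 1;
  if (M < 1) stop("series shorter than one template vector");
  IntegerVector counts(M);
  const double *p = REAL(x);
  int *cnt = INTEGER(counts);
  const double r2 = r * r;
  // every template matches itself at distance 0 <= r (r >= 0);
  // remaining pairs are symmetric, so each is tested once
  for (int i = 0; i < M; ++i) cnt[i] = 1;
  for (int i = 0; i < M; ++i) {
    const double *pi = p + i;
    for (int j = i + 1; j < M; ++j) {
      const double *pj = p + j;
      bool ok = true;
      if (chebyshev) {
        for (int k = 0; k < m; ++k) {
          const double d = pi[k] - pj[k];
          if (d > r || -d > r) { ok = false; break; }
        }
      } else {
        double s = 0.0;
        for (int k = 0; k < m; ++k) {
          const double d = pi[k] - pj[k];
          s += d * d;
          if (s > r2) { ok = false; break; }
        }
      }
      if (ok) { ++cnt[i]; ++cnt[j]; }
    }
  }
  return counts;
}
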