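#include <Rcpp.h>
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo recursion on a
// topologically sorted pedigree.  sire/dam are 1-based positions into the
// pedigree (0 = unknown parent).  F_i = A_ii - 1 where A_ii is accumulated
// from the L row of the generalized Cholesky decomposition A = L D L'.
// [[Rcpp::export]]
NumericVector ml_inbreeding_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  std::vector<double> L(n + 1, 0.0);
  std::vector<double> D(n + 1, 0.0);
  for (int i = 1; i <= n; ++i) {
    int s = sire[i - 1], d = dam[i - 1];
    if (s >= i || d >= i)
      stop("pedigree not topologically sorted at record %d", i);
    double dii;
    if (s == 0 && d == 0)      dii = 1.0;
    else if (s == 0)           dii = 0.75 - 0.25 * F[d - 1];
    else if (d == 0)           dii = 0.75 - 0.25 * F[s - 1];
    else                       dii = 0.5 - 0.25 * (F[s - 1] + F[d - 1]);
    D[i] = dii;
    if (s == 0 || d == 0) { F[i - 1] = 0.0; continue; }
    std::fill(L.begin(), L.begin() + i + 1, 0.0);
    L[i] = 1.0;
    double aii = 0.0;
    for (int j = i; j >= 1; --j) {
      double lj = L[j];
      if (lj == 0.0) continue;
      int sj = sire[j - 1], dj = dam[j - 1];
      if (sj > 0) L[sj] += 0.5 * lj;
      if (dj > 0) L[dj] += 0.5 * lj;
      aii += lj * lj * D[j];
    }
    F[i - 1] = aii - 1.0;
  }
  return F;
}
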