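#include <Rcpp.h>
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo recursion.
// sire/dam are 1-based indices into the (topologically ordered) pedigree,
// NA for unknown. Mendelian sampling variances d_j use only F of animals
// preceding j, so a single forward pass suffices.
// [[Rcpp::export(name = "ped_inbreeding_cpp")]]
NumericVector ped_inbreeding(IntegerVector sire, IntegerVector dam, int n) {
  NumericVector F(n, 0.0);
  NumericVector d(n, 1.0);
  std::vector<double> L(n, 0.0);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] == NA_INTEGER ? -1 : sire[i] - 1;
    int dd = dam[i] == NA_INTEGER ? -1 : dam[i] - 1;
    if (s >= i || dd >= i) stop("pedigree not topologically ordered");
    if (s < 0 && dd < 0) {
      d[i] = 1.0;
      F[i] = 0.0;
      continue;
    }
    if (s >= 0 && dd >= 0) d[i] = 0.5 - 0.25 * (F[s] + F[dd]);
    else d[i] = 0.75 - 0.25 * (s >= 0 ? F[s] : F[dd]);
    // A(i,i) = sum_j L_ij^2 d_j over ancestors j of i (including i)
    std::fill(L.begin(), L.begin() + i + 1, 0.0);
    L[i] = 1.0;
    double aii = 0.0;
    for (int j = i; j >= 0; --j) {
      if (L[j] == 0.0) continue;
      int js = sire[j] == NA_INTEGER ? -1 : sire[j] - 1;
      int jd = dam[j] == NA_INTEGER ? -1 : dam[j] - 1;
      if (js >= 0) L[js] += 0.5 * L[j];
      if (jd >= 0) L[jd] += 0.5 * L[j];
      aii += L[j] * L[j] * d[j];
      L[j] = 0.0;
    }
    F[i] = aii - 1.0;
  }
  return F;
}

// Numerator relationship matrix by the tabular method.
// [[Rcpp::export(name = "ped_tabular_A_cpp")]]
NumericMatrix ped_tabular_A(IntegerVector sire, IntegerVector dam, int n) {
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] == NA_INTEGER ? -1 : sire[i] - 1;
    int d = dam[i] == NA_INTEGER ? -1 : dam[i] - 1;
    if (s >= i || d >= i) stop("pedigree not topologically ordered");
    for (int j = 0; j < i; ++j) {
      double a = 0.0;
      if (s >= 0) a += 0.5 * A(s, j);
      if (d >= 0) a += 0.5 * A(d, j);
      A(i, j) = a;
      A(j, i) = a;
    }
    double aii = 1.0;
    if (s >= 0 && d >= 0) aii += 0.5 * A(s, d);
    A(i, i) = aii;
  }
  return A;
}
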