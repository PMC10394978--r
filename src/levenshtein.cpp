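#include <Rcpp.h>
using namespace Rcpp;

// Token-level Levenshtein distance between two integer-coded sequences.
// Two-row dynamic programme; cost 1 for insertion, deletion, substitution.
static int lev_core(const IntegerVector& a, const IntegerVector& b) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
int lev_int(IntegerVector a, IntegerVector b) {
  return lev_core(a, b);
}

// [[Rcpp::export]]
IntegerMatrix lev_matrix_int(List seqs) {
  const int n = seqs.size();
  IntegerMatrix d(n, n);
  std::vector<IntegerVector> v(n);
  for (int i = 0; i < n; ++i) v[i] = as<IntegerVector>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int dij = lev_core(v[i], v[j]);
      d(i, j) = dij;
      d(j, i) = dij;
    }
  }
  return d;
}

// [[Rcpp::export]]
IntegerVector lev_cross_int(List a, List b) {
  // distances between corresponding elements of two equal-length lists
  const int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = lev_core(as<IntegerVector>(a[i]), as<IntegerVector>(b[i]));
  return out;
}
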