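#include <Rcpp.h>
using namespace Rcpp;

// Gather with zero-fill: out[i] = v[idx[i]-1], or 0 where idx[i] == 0.
// idx is 1-based; together with scatter_add_cpp it forms an adjoint pair
// (the backward pass of one is the other).
// [[Rcpp::export]]
NumericVector gather_cpp(NumericVector v, IntegerVector idx) {
  R_xlen_t m = idx.size();
  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    int j = idx[i];
    out[i] = j > 0 ? v[j - 1] : 0.0;
  }
  return out;
}

// Scatter-add: out[idx[i]-1] += v[i]; entries with idx[i] == 0 are dropped.
// [[Rcpp::export]]
NumericVector scatter_add_cpp(NumericVector v, IntegerVector idx, int n) {
  R_xlen_t m = v.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < m; ++i) {
    int j = idx[i];
    if (j > 0) out[j - 1] += v[i];
  }
  return out;
}
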