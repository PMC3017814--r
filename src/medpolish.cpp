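#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median of the first n elements of buf (buf is scratch, reordered)
static double med(std::vector<double> &buf, int n) {
  int h = n / 2;
  std::nth_element(buf.begin(), buf.begin() + h, buf.begin() + n);
  double m = buf[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(buf.begin(), buf.begin() + h);
    m = 0.5 * (m + lo);
  }
  return m;
}

// Median polish of each probe-set block of a row-grouped log2 matrix.
// Rows must be ordered so that block k occupies rows
// [set_start[k], set_start[k] + set_len[k]). Returns the per-set,
// per-sample expression values overall + col_effect. Row sweep first,
// convergence on the total absolute change per iteration.
// [[Rcpp::export]]
NumericMatrix medpolish_sets_cpp(NumericMatrix y, IntegerVector set_start,
                                 IntegerVector set_len, double tol,
                                 int max_iter) {
  int nsets = set_start.size();
  int ns = y.ncol();
  NumericMatrix out(nsets, ns);
  int max_len = 0;
  for (int k = 0; k < nsets; ++k) max_len = std::max(max_len, set_len[k]);
  std::vector<double> r((size_t)max_len * ns);
  std::vector<double> buf(std::max(max_len, ns));
  std::vector<double> row_eff(max_len), col_eff(ns);

  for (int k = 0; k < nsets; ++k) {
    int np = set_len[k];
    int off = set_start[k];
    for (int i = 0; i < np; ++i)
      for (int j = 0; j < ns; ++j) r[(size_t)i * ns + j] = y(off + i, j);
    std::fill(row_eff.begin(), row_eff.begin() + np, 0.0);
    std::fill(col_eff.begin(), col_eff.end(), 0.0);
    double overall = 0.0;
    for (int iter = 0; iter < max_iter; ++iter) {
      double change = 0.0;
      for (int i = 0; i < np; ++i) {
        for (int j = 0; j < ns; ++j) buf[j] = r[(size_t)i * ns + j];
        double m = med(buf, ns);
        row_eff[i] += m;
        for (int j = 0; j < ns; ++j) r[(size_t)i * ns + j] -= m;
        change += std::fabs(m);
      }
      for (int i = 0; i < np; ++i) buf[i] = row_eff[i];
      double delta = med(buf, np);
      overall += delta;
      for (int i = 0; i < np; ++i) row_eff[i] -= delta;
      for (int j = 0; j < ns; ++j) {
        for (int i = 0; i < np; ++i) buf[i] = r[(size_t)i * ns + j];
        double m = med(buf, np);
        col_eff[j] += m;
        for (int i = 0; i < np; ++i) r[(size_t)i * ns + j] -= m;
        change += std::fabs(m);
      }
      for (int j = 0; j < ns; ++j) buf[j] = col_eff[j];
      delta = med(buf, ns);
      overall += delta;
      for (int j = 0; j < ns; ++j) col_eff[j] -= delta;
      if (change < tol) break;
    }
    for (int j = 0; j < ns; ++j) out(k, j) = overall + col_eff[j];
  }
  return out;
}
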