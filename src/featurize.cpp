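#include <Rcpp.h>
using namespace Rcpp;

// Filter-bank features for a batch of square images.
// X: n x (size*size) matrix, column-major pixels per row, already
// standardized per image. Returns n x 4*g*g: per-block means, standard
// deviations, and pooled |horizontal| / |vertical| gradient energies.
// Single pass per image, no large temporaries.
// [[Rcpp::export]]
NumericMatrix ca_filter_bank(NumericMatrix X, int size, int g,
                             bool standardize = false) {
  const int n = X.nrow();
  const int p = X.ncol();
  const int gg = g * g;
  NumericMatrix out(n, 4 * gg);
  std::vector<int> brk(size);
  for (int i = 0; i < size; ++i)
    brk[i] = (int)std::ceil((double)(i + 1) * g / size) - 1;
  std::vector<double> s1(gg), s2(gg), sgx(gg), sgy(gg);
  std::vector<int> cnt(gg, 0);
  for (int c = 0; c < size; ++c)
    for (int r = 0; r < size; ++r)
      cnt[brk[c] * g + brk[r]]++;
  std::vector<double> img(p);
  for (int i = 0; i < n; ++i) {
    double mu = 0.0, sdv = 1.0;
    if (standardize) {
      double a = 0.0, b = 0.0;
      for (int j = 0; j < p; ++j) { a += X(i, j); b += X(i, j) * X(i, j); }
      mu = a / p;
      double var = b / p - mu * mu;
      sdv = var > 1e-24 ? std::sqrt(var) : -1.0;  // flag constant image
    }
    if (sdv < 0) { for (int j = 0; j < p; ++j) img[j] = 0.0; }
    else if (standardize) {
      for (int j = 0; j < p; ++j) img[j] = (X(i, j) - mu) / sdv;
    } else {
      for (int j = 0; j < p; ++j) img[j] = X(i, j);
    }
    std::fill(s1.begin(), s1.end(), 0.0);
    std::fill(s2.begin(), s2.end(), 0.0);
    std::fill(sgx.begin(), sgx.end(), 0.0);
    std::fill(sgy.begin(), sgy.end(), 0.0);
    for (int c = 0; c < size; ++c) {
      const int coff = c * size;
      const int cnext = (c + 1 < size ? c + 1 : c) * size;
      for (int r = 0; r < size; ++r) {
        const double v = img[coff + r];
        const int b = brk[c] * g + brk[r];
        s1[b] += v;
        s2[b] += v * v;
        sgx[b] += std::fabs(img[cnext + r] - v);
        const int rnext = r + 1 < size ? r + 1 : r;
        sgy[b] += std::fabs(img[coff + rnext] - v);
      }
    }
    for (int b = 0; b < gg; ++b) {
      const double m = s1[b] / cnt[b];
      double var = s2[b] / cnt[b] - m * m;
      out(i, b) = m;
      out(i, gg + b) = var > 0 ? std::sqrt(var) : 0.0;
      out(i, 2 * gg + b) = sgx[b] / cnt[b];
      out(i, 3 * gg + b) = sgy[b] / cnt[b];
    }
  }
  return out;
}
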