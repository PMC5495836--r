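#include <Rcpp.h>
using namespace Rcpp;

// One direct-form-II-transposed IIR pass over buf (in place), zero
// initial state; switch-on transients are absorbed by the reflection
// padding of the caller.
static void df2t_pass(std::vector<double>& buf, const NumericVector& b,
                      const NumericVector& a) {
  const int n = buf.size();
  const int m = a.size() - 1;
  std::vector<double> z(m, 0.0);
  for (int t = 0; t < n; ++t) {
    const double x = buf[t];
    const double y = b[0] * x + z[0];
    for (int k = 0; k < m - 1; ++k)
      z[k] = b[k + 1] * x + z[k + 1] - a[k + 1] * y;
    z[m - 1] = b[m] * x - a[m] * y;
    buf[t] = y;
  }
}

// Zero-phase IIR filtering along the rows of X (one time series per row).
// Each series is extended by odd reflection over npad samples at both
// ends, filtered forward and backward, and cropped back. npad must be
// <= ncol(X) - 1; a[0] must be 1 and length(a) == length(b).
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt_rows(NumericMatrix X, NumericVector b,
                                NumericVector a, int npad) {
  const int npx = X.nrow(), nt = X.ncol();
  const int next = nt + 2 * npad;
  std::vector<double> buf(next);
  NumericMatrix Y(npx, nt);
  for (int p = 0; p < npx; ++p) {
    const double x0 = X(p, 0), xn = X(p, nt - 1);
    for (int i = 0; i < npad; ++i) buf[i] = 2.0 * x0 - X(p, npad - i);
    for (int t = 0; t < nt; ++t) buf[npad + t] = X(p, t);
    for (int i = 0; i < npad; ++i) buf[npad + nt + i] = 2.0 * xn - X(p, nt - 2 - i);
    df2t_pass(buf, b, a);
    std::reverse(buf.begin(), buf.end());
    df2t_pass(buf, b, a);
    std::reverse(buf.begin(), buf.end());
    for (int t = 0; t < nt; ++t) Y(p, t) = buf[npad + t];
  }
  return Y;
}

// Connected-component labeling of a binary image, 4- or 8-connectivity.
// Returns an integer matrix; background = 0, components numbered from 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  static const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  static const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  std::vector<int> stack;
  int cur = 0;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (mask(i, j) && lab(i, j) == 0) {
        ++cur;
        lab(i, j) = cur;
        stack.push_back(i + j * h);
        while (!stack.empty()) {
          const int idx = stack.back();
          stack.pop_back();
          const int ci = idx % h, cj = idx / h;
          for (int k = 0; k < nn; ++k) {
            const int ni = ci + dr8[k], nj = cj + dc8[k];
            if (ni >= 0 && ni < h && nj >= 0 && nj < w &&
                mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = cur;
              stack.push_back(ni + nj * h);
            }
          }
        }
      }
    }
  }
  return lab;
}
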