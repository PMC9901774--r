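#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// reflect index into [0, n-1] (edge-mirrored padding)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n - 2;
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - i;
}

// [[Rcpp::export(name = ".bilateral1d_cpp")]]
NumericVector bilateral1d_cpp(NumericVector x, int window, double sigma_s,
                              double sigma_r) {
  int n = x.size();
  int half = window / 2;
  NumericVector out(n);
  std::vector<double> ws(window);
  for (int k = -half; k <= half; ++k)
    ws[k + half] = std::exp(-0.5 * (double)(k * k) / (sigma_s * sigma_s));
  double inv2sr2 = 0.5 / (sigma_r * sigma_r);
  for (int i = 0; i < n; ++i) {
    double num = 0.0, den = 0.0, xi = x[i];
    for (int k = -half; k <= half; ++k) {
      double xj = x[reflect_idx(i + k, n)];
      double dv = xj - xi;
      double w = ws[k + half] * std::exp(-dv * dv * inv2sr2);
      num += w * xj;
      den += w;
    }
    out[i] = num / den;
  }
  return out;
}

// connected-component labeling on a binary mask (column-major matrix),
// 4- or 8-connectivity, BFS flood fill; labels assigned in scan order
// [[Rcpp::export(name = ".label_cc_cpp")]]
IntegerMatrix label_cc_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> qr, qc;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  int nnb = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      qr.clear(); qc.clear();
      qr.push_back(r); qc.push_back(c);
      lab(r, c) = next;
      size_t head = 0;
      while (head < qr.size()) {
        int cr = qr[head], cc = qc[head];
        ++head;
        for (int k = 0; k < nnb; ++k) {
          int rr = cr + dr[k], cc2 = cc + dc[k];
          if (rr < 0 || rr >= nr || cc2 < 0 || cc2 >= nc) continue;
          if (mask(rr, cc2) && lab(rr, cc2) == 0) {
            lab(rr, cc2) = next;
            qr.push_back(rr); qc.push_back(cc2);
          }
        }
      }
    }
  }
  return lab;
}
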