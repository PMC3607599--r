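#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary mask (column-major logical matrix).
// BFS flood fill; connectivity 4 or 8. Labels are 1..k in scan order of the
// first-encountered pixel (column-major), 0 = background.
// [[Rcpp::export(name = ".label_cc")]]
IntegerMatrix label_cc(LogicalMatrix mask, int connectivity = 8) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nn = (connectivity == 4) ? 4 : 8;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < nn; ++k) {
          int qr = pr + dr8[k], qc = pc + dc8[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr + qc * nr);
          }
        }
      }
    }
  }
  return lab;
}

static LogicalMatrix morph_once(const LogicalMatrix& mask, bool erode) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      bool acc = erode;  // AND-identity for erosion, OR-identity for dilation
      for (int dc = -1; dc <= 1 && (erode ? acc : !acc); ++dc) {
        for (int dr = -1; dr <= 1 && (erode ? acc : !acc); ++dr) {
          int qr = r + dr, qc = c + dc;
          bool v;
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc)
            v = false;  // outside the image counts as background
          else
            v = mask(qr, qc);
          if (erode) acc = acc && v; else acc = acc || v;
        }
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// Binary erosion with a 3x3 square structuring element, iterated k times.
// [[Rcpp::export(name = ".erode_bin")]]
LogicalMatrix erode_bin(LogicalMatrix mask, int k = 1) {
  LogicalMatrix cur = mask;
  for (int i = 0; i < k; ++i) cur = morph_once(cur, true);
  return cur;
}

// Binary dilation with a 3x3 square structuring element, iterated k times.
// [[Rcpp::export(name = ".dilate_bin")]]
LogicalMatrix dilate_bin(LogicalMatrix mask, int k = 1) {
  LogicalMatrix cur = mask;
  for (int i = 0; i < k; ++i) cur = morph_once(cur, false);
  return cur;
}
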