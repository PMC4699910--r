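#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label connected components of a binary mask by breadth-first search.
// Labels are assigned in raster-scan order (row by row, left to right), so the
// first-seen component gets label 1; ties on area are broken downstream by
// taking the lowest label.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  std::vector<int> dr, dc;
  dr = {-1, 1, 0, 0};
  dc = {0, 0, -1, 1};
  if (connectivity == 8) {
    int ddr[] = {-1, -1, 1, 1};
    int ddc[] = {-1, 1, -1, 1};
    for (int k = 0; k < 4; ++k) { dr.push_back(ddr[k]); dc.push_back(ddc[k]); }
  }
  int next = 0;
  std::vector<int> qr, qc;
  qr.reserve(nr * nc); qc.reserve(nr * nc);
  // raster scan: rows outer, columns inner
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      qr.clear(); qc.clear();
      qr.push_back(i); qc.push_back(j);
      lab(i, j) = next;
      size_t head = 0;
      while (head < qr.size()) {
        int r = qr[head], c = qc[head]; ++head;
        for (size_t k = 0; k < dr.size(); ++k) {
          int r2 = r + dr[k], c2 = c + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            qr.push_back(r2); qc.push_back(c2);
          }
        }
      }
    }
  }
  return lab;
}

// Binary dilation (erosion) by an explicit offset list; pixels outside the
// image count as background for both operations.
// [[Rcpp::export(name = ".morph_cpp")]]
LogicalMatrix morph_cpp(LogicalMatrix mask, IntegerVector dr, IntegerVector dc,
                        bool dilate) {
  int nr = mask.nrow(), nc = mask.ncol(), K = dr.size();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      bool acc = !dilate;
      for (int k = 0; k < K; ++k) {
        int r = i - dr[k], c = j - dc[k];
        bool v = (r >= 0 && r < nr && c >= 0 && c < nc) ? (bool)mask(r, c) : false;
        if (dilate) { if (v) { acc = true; break; } }
        else        { if (!v) { acc = false; break; } }
      }
      out(i, j) = acc;
    }
  }
  return out;
}
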