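#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a logical matrix by iterative flood fill.
// connectivity: 4 or 8. Labels are assigned 1..n in raster (column-major)
// order of each component's first-seen pixel, so output is deterministic.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(256);
  int next = 0;

  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = (connectivity == 4) ? dr4 : dr8;
  const int *dc = (connectivity == 4) ? dc4 : dc8;
  const int nn = (connectivity == 4) ? 4 : 8;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int pr = idx % nr, pc = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr + qc * nr);
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

static inline int at(const LogicalMatrix &m, int r, int c) {
  if (r < 0 || r >= m.nrow() || c < 0 || c >= m.ncol()) return 0;
  return m(r, c) ? 1 : 0;
}

// Guo-Hall thinning (two-subiteration parallel thinning) to a 1-px-wide,
// 8-connected skeleton. Neighbour order P2..P9 is N, NE, E, SE, S, SW, W,
// NW with rows growing downward, i.e. P2 = (r-1, c). Chosen over
// Zhang-Suen for its weaker end-of-line erosion on bar-shaped objects.
// [[Rcpp::export(name = ".gh_thin")]]
LogicalMatrix gh_thin(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix img = clone(mask);
  std::vector<int> kill;
  bool changed = true;

  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!img(r, c)) continue;
          int p2 = at(img, r - 1, c),     p3 = at(img, r - 1, c + 1);
          int p4 = at(img, r, c + 1),     p5 = at(img, r + 1, c + 1);
          int p6 = at(img, r + 1, c),     p7 = at(img, r + 1, c - 1);
          int p8 = at(img, r, c - 1),     p9 = at(img, r - 1, c - 1);
          int C = ((!p2 && (p3 || p4)) ? 1 : 0) +
                  ((!p4 && (p5 || p6)) ? 1 : 0) +
                  ((!p6 && (p7 || p8)) ? 1 : 0) +
                  ((!p8 && (p9 || p2)) ? 1 : 0);
          if (C != 1) continue;
          int n1 = ((p9 || p2) ? 1 : 0) + ((p3 || p4) ? 1 : 0) +
                   ((p5 || p6) ? 1 : 0) + ((p7 || p8) ? 1 : 0);
          int n2 = ((p2 || p3) ? 1 : 0) + ((p4 || p5) ? 1 : 0) +
                   ((p6 || p7) ? 1 : 0) + ((p8 || p9) ? 1 : 0);
          int n = n1 < n2 ? n1 : n2;
          if (n < 2 || n > 3) continue;
          int m = (pass == 0) ? (((p6 || p7 || !p9) && p8) ? 1 : 0)
                              : (((p2 || p3 || !p5) && p4) ? 1 : 0);
          if (m != 0) continue;
          kill.push_back(r + c * nr);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k)
        img[kill[k]] = FALSE;
    }
  }
  return img;
}
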