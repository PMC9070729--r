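#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 2D convolution with an odd-sized kernel, border handled by edge replication.
// [[Rcpp::export]]
NumericMatrix conv2_replicate(NumericMatrix img, NumericMatrix kernel) {
  int nr = img.nrow(), nc = img.ncol();
  int kr = kernel.nrow(), kc = kernel.ncol();
  int hr = kr / 2, hc = kc / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int a = 0; a < kr; ++a) {
        int ii = i + a - hr;
        if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        for (int b = 0; b < kc; ++b) {
          int jj = j + b - hc;
          if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
          s += img(ii, jj) * kernel(a, b);
        }
      }
      out(i, j) = s;
    }
  }
  return out;
}

// Grayscale erosion (min) / dilation (max) with a boolean structuring element
// centered on each pixel; the neighborhood is clipped at image borders, which
// for disk and square elements equals edge replication.
// [[Rcpp::export]]
NumericMatrix morph_op(NumericMatrix img, LogicalMatrix se, bool dilate) {
  int nr = img.nrow(), nc = img.ncol();
  int kr = se.nrow(), kc = se.ncol();
  int hr = kr / 2, hc = kc / 2;
  // precompute active offsets
  std::vector<int> da, db;
  for (int a = 0; a < kr; ++a)
    for (int b = 0; b < kc; ++b)
      if (se(a, b)) { da.push_back(a - hr); db.push_back(b - hc); }
  int m = (int) da.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = dilate ? R_NegInf : R_PosInf;
      for (int k = 0; k < m; ++k) {
        int ii = i + da[k];
        if (ii < 0 || ii >= nr) continue;
        int jj = j + db[k];
        if (jj < 0 || jj >= nc) continue;
        double x = img(ii, jj);
        if (dilate) { if (x > v) v = x; } else { if (x < v) v = x; }
      }
      out(i, j) = v;
    }
  }
  return out;
}

// Connected-component labelling of a binary mask (4- or 8-connectivity).
// Labels are assigned in raster-scan order of first encounter, starting at 1.
// [[Rcpp::export]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  static const int d4r[] = {-1, 1, 0, 0};
  static const int d4c[] = {0, 0, -1, 1};
  static const int d8r[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  static const int d8c[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = (connectivity == 8) ? d8r : d4r;
  const int *dc = (connectivity == 8) ? d8c : d4c;
  int nd = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nd; ++k) {
          int qi = pi + dr[k], qj = pj + dc[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// --- fast exact morphology ---------------------------------------------
// Sliding 1D min/max along each row (window = column range [j-w, j+w],
// clipped at borders), monotonic-deque algorithm, O(1) amortized per pixel.
static void slide_rows(const NumericMatrix &in, NumericMatrix &out,
                       int w, bool maxop) {
  int nr = in.nrow(), nc = in.ncol();
  std::vector<int> dq(nc);
  for (int i = 0; i < nr; ++i) {
    int head = 0, tail = 0;  // dq[head..tail) holds candidate column indices
    int p = 0;               // next output column
    for (int j = 0; j < nc + w; ++j) {
      if (j < nc) {
        double x = in(i, j);
        while (tail > head) {
          double y = in(i, dq[tail - 1]);
          if (maxop ? (y <= x) : (y >= x)) --tail; else break;
        }
        dq[tail++] = j;
      }
      if (j >= w) {
        while (dq[head] < p - w) ++head;
        out(i, p) = in(i, dq[head]);
        ++p;
      }
    }
  }
}

// Grayscale erosion/dilation by a flat disk of radius r, exact: the disk is
// the union of horizontal chords of half-width floor(sqrt(r^2 - dy^2)) at
// vertical offsets dy in [-r, r]; min/max over the disk = vertical min/max
// of row-filtered images. Border neighborhoods are clipped (edge
// replication for convex elements).
// [[Rcpp::export]]
NumericMatrix morph_disk(NumericMatrix img, int r, bool dilate) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> width(2 * r + 1);
  int maxw = 0;
  for (int dy = -r; dy <= r; ++dy) {
    int w = (int) std::floor(std::sqrt((double) r * r - (double) dy * dy));
    width[dy + r] = w;
    if (w > maxw) maxw = w;
  }
  // row-filtered image per unique half-width
  std::vector<NumericMatrix> rowpass(maxw + 1);
  std::vector<bool> have(maxw + 1, false);
  for (int dy = -r; dy <= r; ++dy) {
    int w = width[dy + r];
    if (!have[w]) {
      NumericMatrix m(nr, nc);
      slide_rows(img, m, w, dilate);
      rowpass[w] = m;
      have[w] = true;
    }
  }
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = dilate ? R_NegInf : R_PosInf;
      int lo = std::max(-r, -i), hi = std::min(r, nr - 1 - i);
      for (int dy = lo; dy <= hi; ++dy) {
        double x = rowpass[width[dy + r]](i + dy, j);
        if (dilate) { if (x > v) v = x; } else { if (x < v) v = x; }
      }
      out(i, j) = v;
    }
  }
  return out;
}

// Grayscale erosion/dilation by an odd k x k square: separable 1D passes.
// [[Rcpp::export]]
NumericMatrix morph_square(NumericMatrix img, int k, bool dilate) {
  int nr = img.nrow(), nc = img.ncol();
  int w = k / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  slide_rows(img, tmp, w, dilate);
  // vertical pass: transpose trick avoided, direct deque over rows
  std::vector<int> dq(nr);
  for (int j = 0; j < nc; ++j) {
    int head = 0, tail = 0, p = 0;
    for (int i = 0; i < nr + w; ++i) {
      if (i < nr) {
        double x = tmp(i, j);
        while (tail > head) {
          double y = tmp(dq[tail - 1], j);
          if (dilate ? (y <= x) : (y >= x)) --tail; else break;
        }
        dq[tail++] = i;
      }
      if (i >= w) {
        while (dq[head] < p - w) ++head;
        out(p, j) = tmp(dq[head], j);
        ++p;
      }
    }
  }
  return out;
}
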