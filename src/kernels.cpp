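#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Per-column rolling-ball baseline: 1-D grayscale opening of each column with
// a semicircular structuring element of radius r sampled at spacing dx.
// Heights h[j] = sqrt(r^2 - (j*dx)^2) for |j*dx| <= r. Erosion then dilation;
// positions where the element sticks out of the profile are skipped (profile
// treated as +Inf outside), the standard boundary rule for openings.
// [[Rcpp::export(name = ".rolling_ball_cols")]]
NumericMatrix rolling_ball_cols(const NumericMatrix& img, double r, double dx) {
  if (r <= 0) stop("ball radius must be > 0");
  if (dx <= 0) stop("sample spacing must be > 0");
  const int nr = img.nrow(), nc = img.ncol();
  const int m = (int)std::floor(r / dx);
  std::vector<double> h(2 * m + 1);
  for (int j = -m; j <= m; ++j)
    h[j + m] = std::sqrt(r * r - (j * dx) * (j * dx));
  NumericMatrix out(nr, nc);
  std::vector<double> ero(nr);
  for (int c = 0; c < nc; ++c) {
    for (int i = 0; i < nr; ++i) {
      double e = R_PosInf;
      for (int j = -m; j <= m; ++j) {
        int k = i + j;
        if (k < 0 || k >= nr) continue;
        double v = img(k, c) - h[j + m];
        if (v < e) e = v;
      }
      ero[i] = e;
    }
    for (int i = 0; i < nr; ++i) {
      double d = R_NegInf;
      for (int j = -m; j <= m; ++j) {
        int k = i - j;
        if (k < 0 || k >= nr) continue;
        double v = ero[k] + h[j + m];
        if (v > d) d = v;
      }
      out(i, c) = d;
    }
  }
  return out;
}

// 3x3 median filter with replicate border padding.
// [[Rcpp::export(name = ".median_filter3")]]
NumericMatrix median_filter3(const NumericMatrix& img) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double w[9];
  for (int c = 0; c < nc; ++c) {
    for (int i = 0; i < nr; ++i) {
      int n = 0;
      for (int dc = -1; dc <= 1; ++dc) {
        int cc = std::min(std::max(c + dc, 0), nc - 1);
        for (int dr = -1; dr <= 1; ++dr) {
          int rr = std::min(std::max(i + dr, 0), nr - 1);
          w[n++] = img(rr, cc);
        }
      }
      std::nth_element(w, w + 4, w + 9);
      out(i, c) = w[4];
    }
  }
  return out;
}

// Connected-component labelling of a logical mask, 4- or 8-connectivity.
// Iterative flood fill (explicit stack); labels are 1-based in raster order
// of each component's first-encountered pixel.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(const LogicalMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int, int>> stack;
  int next = 0;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  for (int c = 0; c < nc; ++c) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, c) || lab(i, c)) continue;
      ++next;
      stack.clear();
      stack.emplace_back(i, c);
      lab(i, c) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int k = 0; k < nn; ++k) {
          int rr = p.first + dr8[k], cc = p.second + dc8[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            stack.emplace_back(rr, cc);
          }
        }
      }
    }
  }
  return lab;
}

// Normalized cross-correlation over integer shifts (dr, dc) in
// [-max_shift, max_shift]^2. For each shift the red grid is displaced by
// (dr, dc) and the Pearson correlation of the overlapping region with the
// blue grid is computed. `stride` sub-samples the overlap grid (the peak
// location is unchanged; only the pixel count entering each correlation
// shrinks). Returns a (2*max_shift+1)^2 x 3 matrix with columns
// (dr, dc, ncc).
// [[Rcpp::export(name = ".xcorr_grid")]]
NumericMatrix xcorr_grid(const NumericMatrix& blue, const NumericMatrix& red,
                         int max_shift, int stride = 1) {
  const int nr = blue.nrow(), nc = blue.ncol();
  if (red.nrow() != nr || red.ncol() != nc)
    stop("channel grids must have identical shape");
  const int w = 2 * max_shift + 1;
  NumericMatrix out(w * w, 3);
  int row = 0;
  for (int dr = -max_shift; dr <= max_shift; ++dr) {
    for (int dc = -max_shift; dc <= max_shift; ++dc, ++row) {
      // hypothesis: red content is displaced by (dr, dc) relative to blue,
      // i.e. red(i + dr, j + dc) overlays blue(i, j)
      int r0 = std::max(0, -dr), r1 = std::min(nr, nr - dr);
      int c0 = std::max(0, -dc), c1 = std::min(nc, nc - dc);
      double sb = 0, sr = 0, sbb = 0, srr = 0, sbr = 0;
      long n = 0;
      for (int j = c0; j < c1; j += stride) {
        for (int i = r0; i < r1; i += stride) {
          double b = blue(i, j), rv = red(i + dr, j + dc);
          sb += b; sr += rv; sbb += b * b; srr += rv * rv; sbr += b * rv;
          ++n;
        }
      }
      double vb = sbb - sb * sb / n, vr = srr - sr * sr / n;
      double cov = sbr - sb * sr / n;
      double ncc = (vb > 0 && vr > 0) ? cov / std::sqrt(vb * vr) : NA_REAL;
      out(row, 0) = dr;
      out(row, 1) = dc;
      out(row, 2) = ncc;
    }
  }
  return out;
}
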