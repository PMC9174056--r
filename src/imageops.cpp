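#include <Rcpp.h>
#include <stack>
using namespace Rcpp;

// Separable convolution with reflect-101 boundary handling.
// kx is applied along columns (x), ky along rows (y). Kernels must have odd
// length. Both passes run down contiguous columns (R matrices are
// column-major): the horizontal pass accumulates whole-column axpys.
// [[Rcpp::export]]
NumericMatrix cpp_conv_sep(const NumericMatrix& img, const NumericVector& kx,
                           const NumericVector& ky) {
  const int ny = img.nrow(), nx = img.ncol();
  const int rx = (kx.size() - 1) / 2, ry = (ky.size() - 1) / 2;
  NumericMatrix tmp(ny, nx), out(ny, nx);
  const double* src = img.begin();
  double* t = tmp.begin();

  // vertical pass (within-column, stride 1)
  for (int x = 0; x < nx; ++x) {
    const double* col = src + (size_t)x * ny;
    double* tc = t + (size_t)x * ny;
    for (int y = 0; y < ny; ++y) {
      double s = 0.0;
      for (int k = -ry; k <= ry; ++k) {
        int yy = y + k;
        if (yy < 0) yy = -yy;                 // reflect-101
        if (yy >= ny) yy = 2 * ny - 2 - yy;
        s += col[yy] * ky[k + ry];
      }
      tc[y] = s;
    }
  }
  // horizontal pass: for each output column, axpy contributing columns
  double* o = out.begin();
  for (int x = 0; x < nx; ++x) {
    double* oc = o + (size_t)x * ny;
    for (int k = -rx; k <= rx; ++k) {
      int xx = x + k;
      if (xx < 0) xx = -xx;
      if (xx >= nx) xx = 2 * nx - 2 - xx;
      const double w = kx[k + rx];
      const double* tc = t + (size_t)xx * ny;
      for (int y = 0; y < ny; ++y) oc[y] += w * tc[y];
    }
  }
  return out;
}

// 5-point Laplacian stencil with reflect-101 boundaries.
// [[Rcpp::export]]
NumericMatrix cpp_laplace(const NumericMatrix& img) {
  const int ny = img.nrow(), nx = img.ncol();
  NumericMatrix out(ny, nx);
  const double* s = img.begin();
  double* o = out.begin();
  for (int x = 0; x < nx; ++x) {
    int xm = x > 0 ? x - 1 : 1, xp = x < nx - 1 ? x + 1 : nx - 2;
    const double* c = s + (size_t)x * ny;
    const double* l = s + (size_t)xm * ny;
    const double* r = s + (size_t)xp * ny;
    double* oc = o + (size_t)x * ny;
    for (int y = 0; y < ny; ++y) {
      int ym = y > 0 ? y - 1 : 1, yp = y < ny - 1 ? y + 1 : ny - 2;
      oc[y] = l[y] + r[y] + c[ym] + c[yp] - 4.0 * c[y];
    }
  }
  return out;
}

// 4-connected component labeling of a binary mask; labels are assigned in
// raster order (column-major, matching R matrix layout) so output is
// deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label4(const LogicalMatrix& mask) {
  const int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  int next = 0;
  std::stack<std::pair<int, int> > st;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      ++next;
      st.push(std::make_pair(y, x));
      lab(y, x) = next;
      while (!st.empty()) {
        int cy = st.top().first, cx = st.top().second;
        st.pop();
        const int dy[4] = {-1, 1, 0, 0}, dx[4] = {0, 0, -1, 1};
        for (int d = 0; d < 4; ++d) {
          int yy = cy + dy[d], xx = cx + dx[d];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          if (mask(yy, xx) && lab(yy, xx) == 0) {
            lab(yy, xx) = next;
            st.push(std::make_pair(yy, xx));
          }
        }
      }
    }
  }
  return lab;
}

// Strict-or-equal 3x3 local maxima above a threshold. Returns an n x 3 matrix
// of (row, col, value), 1-based indices, ordered by (col, row).
// [[Rcpp::export]]
NumericMatrix cpp_local_max(const NumericMatrix& resp, double thr) {
  const int ny = resp.nrow(), nx = resp.ncol();
  std::vector<double> ys, xs, vs;
  for (int x = 1; x < nx - 1; ++x) {
    for (int y = 1; y < ny - 1; ++y) {
      double v = resp(y, x);
      if (v <= thr) continue;
      bool ismax = true;
      for (int dx = -1; dx <= 1 && ismax; ++dx)
        for (int dy = -1; dy <= 1; ++dy) {
          if (dx == 0 && dy == 0) continue;
          double u = resp(y + dy, x + dx);
          // break plateaus deterministically: earlier (col,row) wins
          if (u > v || (u == v && (dx < 0 || (dx == 0 && dy < 0)))) {
            ismax = false;
            break;
          }
        }
      if (ismax) {
        ys.push_back(y + 1);
        xs.push_back(x + 1);
        vs.push_back(v);
      }
    }
  }
  NumericMatrix out(ys.size(), 3);
  for (size_t i = 0; i < ys.size(); ++i) {
    out(i, 0) = ys[i];
    out(i, 1) = xs[i];
    out(i, 2) = vs[i];
  }
  return out;
}

// Binary dilation with a disk structuring element of radius r (pixels).
// [[Rcpp::export]]
LogicalMatrix cpp_dilate(const LogicalMatrix& mask, int r) {
  const int ny = mask.nrow(), nx = mask.ncol();
  LogicalMatrix out(ny, nx);
  const int r2 = r * r;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      if (!mask(y, x)) continue;
      for (int dx = -r; dx <= r; ++dx)
        for (int dy = -r; dy <= r; ++dy) {
          if (dx * dx + dy * dy > r2) continue;
          int yy = y + dy, xx = x + dx;
          if (yy >= 0 && yy < ny && xx >= 0 && xx < nx) out(yy, xx) = true;
        }
    }
  return out;
}

// Binary erosion with a disk structuring element of radius r (pixels).
// [[Rcpp::export]]
LogicalMatrix cpp_erode(const LogicalMatrix& mask, int r) {
  const int ny = mask.nrow(), nx = mask.ncol();
  LogicalMatrix out(ny, nx);
  const int r2 = r * r;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      if (!mask(y, x)) continue;
      bool keep = true;
      for (int dx = -r; dx <= r && keep; ++dx)
        for (int dy = -r; dy <= r; ++dy) {
          if (dx * dx + dy * dy > r2) continue;
          int yy = y + dy, xx = x + dx;
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || !mask(yy, xx)) {
            keep = false;
            break;
          }
        }
      out(y, x) = keep;
    }
  return out;
}
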