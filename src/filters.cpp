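#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// 3D median filter with per-axis half-widths (rz, ry, rx); replicate padding.
// arr is a numeric vector in column-major (z fastest) order with dims (nz, ny, nx).
// [[Rcpp::export(name = ".median3d_cpp")]]
NumericVector median3d_cpp(NumericVector arr, IntegerVector dim,
                           int rz, int ry, int rx) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out(arr.size());
  std::vector<double> buf;
  buf.reserve((2 * rz + 1) * (2 * ry + 1) * (2 * rx + 1));
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        buf.clear();
        for (int dx = -rx; dx <= rx; ++dx) {
          int xx = std::min(std::max(x + dx, 0), nx - 1);
          for (int dy = -ry; dy <= ry; ++dy) {
            int yy = std::min(std::max(y + dy, 0), ny - 1);
            for (int dz = -rz; dz <= rz; ++dz) {
              int zz = std::min(std::max(z + dz, 0), nz - 1);
              buf.push_back(arr[zz + nz * (yy + (R_xlen_t)ny * xx)]);
            }
          }
        }
        size_t mid = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        double med = buf[mid];
        if (buf.size() % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + mid - 1, buf.begin() + mid);
          med = 0.5 * (med + buf[mid - 1]);
        }
        out[z + nz * (y + (R_xlen_t)ny * x)] = med;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

static inline int px(const IntegerMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c) ? 1 : 0;
}

// Zhang-Suen thinning of a binary 2D mask; returns the one-pixel skeleton.
// [[Rcpp::export(name = ".thin2d_cpp")]]
IntegerMatrix thin2d_cpp(IntegerMatrix mask) {
  IntegerMatrix img = clone(mask);
  const int nr = img.nrow(), nc = img.ncol();
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!img(r, c)) continue;
          // neighbours P2..P9 clockwise starting north
          int p2 = px(img, r - 1, c), p3 = px(img, r - 1, c + 1);
          int p4 = px(img, r, c + 1), p5 = px(img, r + 1, c + 1);
          int p6 = px(img, r + 1, c), p7 = px(img, r + 1, c - 1);
          int p8 = px(img, r, c - 1), p9 = px(img, r - 1, c - 1);
          int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int a = 0;
          int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          for (int k = 0; k < 8; ++k) if (seq[k] == 0 && seq[k + 1] == 1) ++a;
          if (a != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k) img(kill[k].first, kill[k].second) = 0;
    }
  }
  return img;
}
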