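#include <Rcpp.h>
using namespace Rcpp;

// Direct 3x3 / 3x3x3 convolutions with zero ("same") padding on
// channels-last batches: X2 is [N, H, W, C], X3 is [N, D, H, W, C],
// stored column-major (batch index fastest). Shift-and-accumulate loops
// with a contiguous inner loop over the batch dimension.

// [[Rcpp::export(name = ".conv2_fw_cpp")]]
NumericVector conv2_fw_cpp(NumericVector X, IntegerVector xd,
                           NumericVector W, NumericVector b) {
  const int N = xd[0], H = xd[1], Wd = xd[2], Ci = xd[3];
  const int Co = b.size();
  NumericVector Y((R_xlen_t)N * H * Wd * Co);
  const R_xlen_t sH = N, sW = (R_xlen_t)N * H, sC = (R_xlen_t)N * H * Wd;
  for (int co = 0; co < Co; ++co) {
    double *y0 = &Y[0] + sC * co;
    for (R_xlen_t t = 0; t < sC; ++t) y0[t] = b[co];
    for (int ci = 0; ci < Ci; ++ci) {
      const double *x0 = &X[0] + sC * ci;
      for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) {
        const double wv = W[i + 3 * (j + 3 * (ci + (R_xlen_t)Ci * co))];
        if (wv == 0.0) continue;
        const int di = i - 1, dj = j - 1;
        const int h0 = std::max(0, -di), h1 = std::min(H, H - di);
        const int w0 = std::max(0, -dj), w1 = std::min(Wd, Wd - dj);
        const R_xlen_t span = (R_xlen_t)N * (h1 - h0);
        for (int w = w0; w < w1; ++w) {
          double *__restrict yp = y0 + sH * h0 + sW * w;
          const double *__restrict xp = x0 + sH * (h0 + di) + sW * (w + dj);
          for (R_xlen_t t = 0; t < span; ++t) yp[t] += wv * xp[t];
        }
      }
    }
  }
  Y.attr("dim") = IntegerVector::create(N, H, Wd, Co);
  return Y;
}

// [[Rcpp::export(name = ".conv2_bw_cpp")]]
List conv2_bw_cpp(NumericVector X, IntegerVector xd, NumericVector W,
                  IntegerVector wd, NumericVector dY) {
  const int N = xd[0], H = xd[1], Wd = xd[2], Ci = xd[3];
  const int Co = wd[3];
  NumericVector dX(X.size()), dW(W.size()), db(Co);
  const R_xlen_t sH = N, sW = (R_xlen_t)N * H, sC = (R_xlen_t)N * H * Wd;
  for (int co = 0; co < Co; ++co) {
    const double *g0 = &dY[0] + sC * co;
    double acc = 0;
    for (R_xlen_t t = 0; t < sC; ++t) acc += g0[t];
    db[co] = acc;
    for (int ci = 0; ci < Ci; ++ci) {
      const double *x0 = &X[0] + sC * ci;
      double *dx0 = &dX[0] + sC * ci;
      for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) {
        const double wv = W[i + 3 * (j + 3 * (ci + (R_xlen_t)Ci * co))];
        const int di = i - 1, dj = j - 1;
        const int h0 = std::max(0, -di), h1 = std::min(H, H - di);
        const int w0 = std::max(0, -dj), w1 = std::min(Wd, Wd - dj);
        double gw = 0;
        const R_xlen_t span = (R_xlen_t)N * (h1 - h0);
        for (int w = w0; w < w1; ++w) {
          const double *__restrict gp = g0 + sH * h0 + sW * w;
          const double *__restrict xp = x0 + sH * (h0 + di) + sW * (w + dj);
          double *__restrict dxp = dx0 + sH * (h0 + di) + sW * (w + dj);
          for (R_xlen_t t = 0; t < span; ++t) {
            gw += gp[t] * xp[t];
            dxp[t] += gp[t] * wv;
          }
        }
        dW[i + 3 * (j + 3 * (ci + (R_xlen_t)Ci * co))] = gw;
      }
    }
  }
  dX.attr("dim") = xd;
  IntegerVector wdim = IntegerVector::create(3, 3, Ci, Co);
  dW.attr("dim") = wdim;
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".conv3_fw_cpp")]]
NumericVector conv3_fw_cpp(NumericVector X, IntegerVector xd,
                           NumericVector W, NumericVector b) {
  const int N = xd[0], D = xd[1], H = xd[2], Wd = xd[3], Ci = xd[4];
  const int Co = b.size();
  NumericVector Y((R_xlen_t)N * D * H * Wd * Co);
  const R_xlen_t sD = N, sH = (R_xlen_t)N * D, sW = (R_xlen_t)N * D * H,
                 sC = (R_xlen_t)N * D * H * Wd;
  for (int co = 0; co < Co; ++co) {
    double *y0 = &Y[0] + sC * co;
    for (R_xlen_t t = 0; t < sC; ++t) y0[t] = b[co];
    for (int ci = 0; ci < Ci; ++ci) {
      const double *x0 = &X[0] + sC * ci;
      for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j)
      for (int k = 0; k < 3; ++k) {
        const double wv = W[i + 3 * (j + 3 * (k + 3 * (ci + (R_xlen_t)Ci * co)))];
        if (wv == 0.0) continue;
        const int di = i - 1, dj = j - 1, dk = k - 1;
        const int d0 = std::max(0, -di), d1 = std::min(D, D - di);
        const int h0 = std::max(0, -dj), h1 = std::min(H, H - dj);
        const int w0 = std::max(0, -dk), w1 = std::min(Wd, Wd - dk);
        const R_xlen_t span = (R_xlen_t)N * (d1 - d0);
        for (int w = w0; w < w1; ++w) for (int h = h0; h < h1; ++h) {
          double *__restrict yq = y0 + sH * h + sW * w + sD * d0;
          const double *__restrict xq = x0 + sH * (h + dj) + sW * (w + dk) +
            sD * (d0 + di);
          for (R_xlen_t t = 0; t < span; ++t) yq[t] += wv * xq[t];
        }
      }
    }
  }
  Y.attr("dim") = IntegerVector::create(N, D, H, Wd, Co);
  return Y;
}

// [[Rcpp::export(name = ".conv3_bw_cpp")]]
List conv3_bw_cpp(NumericVector X, IntegerVector xd, NumericVector W,
                  IntegerVector wd, NumericVector dY) {
  const int N = xd[0], D = xd[1], H = xd[2], Wd = xd[3], Ci = xd[4];
  const int Co = wd[4];
  NumericVector dX(X.size()), dW(W.size()), db(Co);
  const R_xlen_t sD = N, sH = (R_xlen_t)N * D, sW = (R_xlen_t)N * D * H,
                 sC = (R_xlen_t)N * D * H * Wd;
  for (int co = 0; co < Co; ++co) {
    const double *g0 = &dY[0] + sC * co;
    double acc = 0;
    for (R_xlen_t t = 0; t < sC; ++t) acc += g0[t];
    db[co] = acc;
    for (int ci = 0; ci < Ci; ++ci) {
      const double *x0 = &X[0] + sC * ci;
      double *dx0 = &dX[0] + sC * ci;
      for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j)
      for (int k = 0; k < 3; ++k) {
        const double wv = W[i + 3 * (j + 3 * (k + 3 * (ci + (R_xlen_t)Ci * co)))];
        const int di = i - 1, dj = j - 1, dk = k - 1;
        const int d0 = std::max(0, -di), d1 = std::min(D, D - di);
        const int h0 = std::max(0, -dj), h1 = std::min(H, H - dj);
        const int w0 = std::max(0, -dk), w1 = std::min(Wd, Wd - dk);
        double gw = 0;
        const R_xlen_t span = (R_xlen_t)N * (d1 - d0);
        for (int w = w0; w < w1; ++w) for (int h = h0; h < h1; ++h) {
          const double *__restrict gq = g0 + sH * h + sW * w + sD * d0;
          const double *__restrict xq = x0 + sH * (h + dj) + sW * (w + dk) +
            sD * (d0 + di);
          double *__restrict dxq = dx0 + sH * (h + dj) + sW * (w + dk) +
            sD * (d0 + di);
          for (R_xlen_t t = 0; t < span; ++t) {
            gw += gq[t] * xq[t];
            dxq[t] += gq[t] * wv;
          }
        }
        dW[i + 3 * (j + 3 * (k + 3 * (ci + (R_xlen_t)Ci * co)))] = gw;
      }
    }
  }
  dX.attr("dim") = xd;
  dW.attr("dim") = wd;
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}
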