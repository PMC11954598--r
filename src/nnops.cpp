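// im2col / col2im for 3x3 same-padding convolutions on (H, W, C) arrays.
// The hot path of the pure-R network: gathering shifted copies of the
// padded feature map into the patch matrix consumed by BLAS.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export(name = ".im2col3_cpp")]]
NumericMatrix im2col3_cpp(NumericVector x, int H, int W, int C) {
  NumericMatrix out(H * W, 9 * C);
  double* po = out.begin();
  const double* px = x.begin();
  int col = 0;
  for (int dj = 0; dj < 3; ++dj) {
    for (int di = 0; di < 3; ++di) {
      for (int c = 0; c < C; ++c, ++col) {
        double* o = po + (size_t)col * H * W;
        const double* xc = px + (size_t)c * H * W;
        for (int j = 0; j < W; ++j) {
          int sj = j + dj - 1;  // source column in the unpadded map
          double* ocol = o + (size_t)j * H;
          if (sj < 0 || sj >= W) {
            for (int i = 0; i < H; ++i) ocol[i] = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)sj * H;
          // shift by di-1 within the column; pad the exposed end with 0
          if (di == 0) {            // source rows -1..H-2
            ocol[0] = 0.0;
            std::memcpy(ocol + 1, xcol, (H - 1) * sizeof(double));
          } else if (di == 1) {     // aligned
            std::memcpy(ocol, xcol, H * sizeof(double));
          } else {                  // source rows 1..H
            std::memcpy(ocol, xcol + 1, (H - 1) * sizeof(double));
            ocol[H - 1] = 0.0;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".col2im3_cpp")]]
NumericVector col2im3_cpp(NumericMatrix dcol, int H, int W, int C) {
  NumericVector dx((size_t)H * W * C);
  double* pd = dx.begin();
  const double* pc = dcol.begin();
  int col = 0;
  for (int dj = 0; dj < 3; ++dj) {
    for (int di = 0; di < 3; ++di) {
      for (int c = 0; c < C; ++c, ++col) {
        const double* src = pc + (size_t)col * H * W;
        double* dxc = pd + (size_t)c * H * W;
        for (int j = 0; j < W; ++j) {
          int sj = j + dj - 1;
          if (sj < 0 || sj >= W) continue;
          const double* scol = src + (size_t)j * H;
          double* dcolv = dxc + (size_t)sj * H;
          for (int i = 0; i < H; ++i) {
            int si = i + di - 1;
            if (si >= 0 && si < H) dcolv[si] += scol[i];
          }
        }
      }
    }
  }
  return dx;
}
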