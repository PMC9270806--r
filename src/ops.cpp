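#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Neighbourhood table for a 3D convolution over a (h, w, t) grid stored in
// column-major linear order (h fastest). Entry nb(k, p) is the 1-based linear
// index of the input voxel feeding kernel offset k at output position p, or 0
// when the offset falls outside the grid under zero padding. Reflection
// padding folds out-of-range coordinates back (no edge repeat), so 0 never
// occurs in reflect mode provided pad < dim.
// [[Rcpp::export]]
IntegerMatrix cpp_build_nb(IntegerVector dims, IntegerVector kernel,
                           IntegerVector stride, IntegerVector pad_lo,
                           IntegerVector pad_hi, bool reflect) {
  const int h = dims[0], w = dims[1], t = dims[2];
  const int kh = kernel[0], kw = kernel[1], kt = kernel[2];
  const int sh = stride[0], sw = stride[1], st = stride[2];
  const int oh = (h + pad_lo[0] + pad_hi[0] - kh) / sh + 1;
  const int ow = (w + pad_lo[1] + pad_hi[1] - kw) / sw + 1;
  const int ot = (t + pad_lo[2] + pad_hi[2] - kt) / st + 1;
  if (oh < 1 || ow < 1 || ot < 1)
    stop("input grid smaller than the kernel's minimum extent");
  const int K = kh * kw * kt;
  const R_xlen_t P = (R_xlen_t)oh * ow * ot;
  IntegerMatrix nb(K, P);
  auto fold = [reflect](int c, int n) -> int {
    if (c >= 0 && c < n) return c;
    if (!reflect) return -1;
    if (c < 0) c = -c;
    if (c >= n) c = 2 * n - 2 - c;
    return (c >= 0 && c < n) ? c : -1;
  };
  R_xlen_t p = 0;
  for (int ct = 0; ct < ot; ++ct) {
    for (int cw = 0; cw < ow; ++cw) {
      for (int ch = 0; ch < oh; ++ch, ++p) {
        const int bh = ch * sh - pad_lo[0];
        const int bw = cw * sw - pad_lo[1];
        const int bt = ct * st - pad_lo[2];
        int k = 0;
        for (int dt = 0; dt < kt; ++dt) {
          const int it = fold(bt + dt, t);
          for (int dw = 0; dw < kw; ++dw) {
            const int iw = fold(bw + dw, w);
            for (int dh = 0; dh < kh; ++dh, ++k) {
              const int ih = fold(bh + dh, h);
              if (ih < 0 || iw < 0 || it < 0) {
                nb(k, p) = 0;
              } else {
                nb(k, p) = 1 + ih + (R_xlen_t)h * (iw + (R_xlen_t)w * it);
              }
            }
          }
        }
      }
    }
  }
  nb.attr("out_dims") = IntegerVector::create(oh, ow, ot);
  return nb;
}

// Gather feature columns: X is C x N (channels x voxels), nb is K x P.
// Returns the (C*K) x P patch matrix with channel running fastest in rows.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericMatrix X, IntegerMatrix nb) {
  const int C = X.nrow();
  const int K = nb.nrow();
  const R_xlen_t P = nb.ncol();
  NumericMatrix out(C * K, P);
  const double* x = REAL(X);
  double* o = REAL(out);
  const int* nbp = INTEGER(nb);
  for (R_xlen_t p = 0; p < P; ++p) {
    double* col = o + (R_xlen_t)C * K * p;
    const int* nbc = nbp + (R_xlen_t)K * p;
    for (int k = 0; k < K; ++k) {
      const int src = nbc[k];
      double* dst = col + (R_xlen_t)C * k;
      if (src == 0) {
        std::fill(dst, dst + C, 0.0);
      } else {
        const double* s = x + (R_xlen_t)C * (src - 1);
        std::copy(s, s + C, dst);
      }
    }
  }
  return out;
}

// Scatter-add transpose of cpp_im2col: accumulates patch gradients back onto
// the C x N input grid. Zero-pad positions (index 0) are dropped.
// [[Rcpp::export]]
NumericMatrix cpp_col2im(NumericMatrix dcols, IntegerMatrix nb, int C, int N) {
  const int K = nb.nrow();
  const R_xlen_t P = nb.ncol();
  if (dcols.nrow() != C * K || dcols.ncol() != P)
    stop("gradient matrix does not match the neighbourhood table");
  NumericMatrix dX(C, N);
  const double* d = REAL(dcols);
  double* o = REAL(dX);
  const int* nbp = INTEGER(nb);
  for (R_xlen_t p = 0; p < P; ++p) {
    const double* col = d + (R_xlen_t)C * K * p;
    const int* nbc = nbp + (R_xlen_t)K * p;
    for (int k = 0; k < K; ++k) {
      const int dst = nbc[k];
      if (dst == 0) continue;
      double* t = o + (R_xlen_t)C * (dst - 1);
      const double* s = col + (R_xlen_t)C * k;
      for (int c = 0; c < C; ++c) t[c] += s[c];
    }
  }
  return dX;
}

// 2D median filter with odd square kernel and replicated borders.
// [[Rcpp::export]]
NumericMatrix cpp_median2d(NumericMatrix X, int k) {
  if (k % 2 == 0 || k < 1) stop("median kernel size must be odd and positive");
  const int h = X.nrow(), w = X.ncol(), r = k / 2;
  NumericMatrix out(h, w);
  std::vector<double> buf(k * k);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      int n = 0;
      for (int dj = -r; dj <= r; ++dj) {
        int cj = std::min(std::max(j + dj, 0), w - 1);
        for (int di = -r; di <= r; ++di) {
          int ci = std::min(std::max(i + di, 0), h - 1);
          buf[n++] = X(ci, cj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
      double med = buf[n / 2];
      if (n % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + n / 2 - 1, buf.begin() + n / 2);
        med = 0.5 * (med + buf[n / 2 - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Direct 3D convolution forward for wide kernels (avoids materializing the
// im2col buffer). X is C x N, W is Cout x (C*K) with channel fastest, nb the
// neighbourhood table. Returns Cout x P.
// [[Rcpp::export]]
NumericMatrix cpp_conv3d_direct(NumericMatrix X, NumericMatrix W,
                                NumericVector b, IntegerMatrix nb) {
  const int C = X.nrow();
  const int K = nb.nrow();
  const R_xlen_t P = nb.ncol();
  const int Cout = W.nrow();
  if (W.ncol() != C * K) stop("weight shape does not match C*K");
  NumericMatrix out(Cout, P);
  const double* x = REAL(X);
  const double* w = REAL(W);
  double* o = REAL(out);
  const int* nbp = INTEGER(nb);
  std::vector<double> acc(Cout);
  for (R_xlen_t p = 0; p < P; ++p) {
    for (int co = 0; co < Cout; ++co) acc[co] = b[co];
    const int* nbc = nbp + (R_xlen_t)K * p;
    for (int k = 0; k < K; ++k) {
      const int src = nbc[k];
      if (src == 0) continue;
      const double* xs = x + (R_xlen_t)C * (src - 1);
      const double* wk = w + (R_xlen_t)Cout * C * k;
      for (int c = 0; c < C; ++c) {
        const double xv = xs[c];
        const double* wc = wk + (R_xlen_t)Cout * c;
        for (int co = 0; co < Cout; ++co) acc[co] += wc[co] * xv;
      }
    }
    double* op = o + (R_xlen_t)Cout * p;
    for (int co = 0; co < Cout; ++co) op[co] = acc[co];
  }
  return out;
}

// Direct backward pass companion: accumulates dX (C x N), dW and db from the
// upstream gradient dY (Cout x P).
// [[Rcpp::export]]
List cpp_conv3d_direct_bwd(NumericMatrix X, NumericMatrix W,
                           NumericMatrix dY, IntegerMatrix nb, int N) {
  const int C = X.nrow();
  const int K = nb.nrow();
  const R_xlen_t P = nb.ncol();
  const int Cout = W.nrow();
  NumericMatrix dX(C, N), dW(Cout, C * K);
  NumericVector db(Cout);
  const double* x = REAL(X);
  const double* w = REAL(W);
  const double* dy = REAL(dY);
  double* dxp = REAL(dX);
  double* dwp = REAL(dW);
  const int* nbp = INTEGER(nb);
  for (R_xlen_t p = 0; p < P; ++p) {
    const double* dyp = dy + (R_xlen_t)Cout * p;
    for (int co = 0; co < Cout; ++co) db[co] += dyp[co];
    const int* nbc = nbp + (R_xlen_t)K * p;
    for (int k = 0; k < K; ++k) {
      const int src = nbc[k];
      if (src == 0) continue;
      const double* xs = x + (R_xlen_t)C * (src - 1);
      double* dxs = dxp + (R_xlen_t)C * (src - 1);
      const double* wk = w + (R_xlen_t)Cout * C * k;
      double* dwk = dwp + (R_xlen_t)Cout * C * k;
      for (int c = 0; c < C; ++c) {
        const double xv = xs[c];
        const double* wc = wk + (R_xlen_t)Cout * c;
        double* dwc = dwk + (R_xlen_t)Cout * c;
        double accx = 0.0;
        for (int co = 0; co < Cout; ++co) {
          const double g = dyp[co];
          accx += wc[co] * g;
          dwc[co] += g * xv;
        }
        dxs[c] += accx;
      }
    }
  }
  return List::create(Named("dX") = dX, Named("dW") = dW, Named("db") = db);
}
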