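// Low-level numerical kernels for the convolutional model.
//
// Layout conventions follow R's column-major arrays:
//   image batch  : (H, W, C, N)
//   conv weights : (k, k, C_in, C_out)
// im2col matrices are built per image as (H*W) x (k*k*C_in) so that the
// convolution is a single dgemm against the (k*k*C_in) x C_out weight matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;

static void im2col_rows(const double* x, int H, int W, int C, int k, int pad,
                        mat& colsT, size_t row0) {
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * HW;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + k * kj + k * k * c;
        double* dst = colsT.colptr(col) + row0;
        for (int j = 0; j < W; ++j) {
          const int jj = j + kj - pad;
          if (jj < 0 || jj >= W) {
            for (int i = 0; i < H; ++i) dst[i + H * j] = 0.0;
            continue;
          }
          const double* src = xc + (size_t)H * jj;
          for (int i = 0; i < H; ++i) {
            const int ii = i + ki - pad;
            dst[i + H * j] = (ii >= 0 && ii < H) ? src[ii] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_t(const mat& colsT, int H, int W, int C, int k, int pad,
                     double* dx) {
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * HW;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + k * kj + k * k * c;
        const double* src = colsT.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int jj = j + kj - pad;
          if (jj < 0 || jj >= W) continue;
          double* dstc = xc + (size_t)H * jj;
          for (int i = 0; i < H; ++i) {
            const int ii = i + ki - pad;
            if (ii >= 0 && ii < H) dstc[ii] += src[i + H * j];
          }
        }
      }
    }
  }
}

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  return d;
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = dims4(x), dw = dims4(w);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], Cin = dw[2], Cout = dw[3];
  if (dw[1] != k) stop("kernel must be square");
  if (Cin != C) stop("input channel mismatch");
  if (b.size() != Cout) stop("bias length mismatch");
  const int pad = (k - 1) / 2;
  const int HW = H * W;

  NumericVector out = alloc4(H, W, Cout, N);
  const mat wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  const arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  // one im2col block per image, stacked row-wise, then a single dgemm
  mat colsT((size_t)N * HW, k * k * Cin);
  for (int n = 0; n < N; ++n)
    im2col_rows(x.begin() + (size_t)n * HW * C, H, W, C, k, pad, colsT,
                (size_t)n * HW);
  mat o_all = colsT * wm;
  o_all.each_row() += bv;
  // scatter rows back into (H, W, Cout, N) layout
  for (int n = 0; n < N; ++n) {
    mat o(out.begin() + (size_t)n * HW * Cout, HW, Cout, false, true);
    o = o_all.rows((size_t)n * HW, (size_t)(n + 1) * HW - 1);
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dout) {
  IntegerVector dx = dims4(x), dw = dims4(w), dd = dims4(dout);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], Cout = dw[3];
  const int pad = (k - 1) / 2;
  const int HW = H * W;
  if (dd[0] != H || dd[1] != W || dd[2] != Cout || dd[3] != N)
    stop("gradient shape mismatch");

  NumericVector dxv = alloc4(H, W, C, N);
  NumericVector dwv = alloc4(k, k, C, Cout);
  NumericVector dbv(Cout);
  const mat wm(const_cast<double*>(w.begin()), k * k * C, Cout, false, true);
  mat dwm(dwv.begin(), k * k * C, Cout, false, true);
  arma::rowvec db(dbv.begin(), Cout, false, true);
  mat colsT((size_t)N * HW, k * k * C);
  mat domAll((size_t)N * HW, Cout);
  for (int n = 0; n < N; ++n) {
    im2col_rows(x.begin() + (size_t)n * HW * C, H, W, C, k, pad, colsT,
                (size_t)n * HW);
    const mat dom(const_cast<double*>(dout.begin()) + (size_t)n * HW * Cout,
                  HW, Cout, false, true);
    domAll.rows((size_t)n * HW, (size_t)(n + 1) * HW - 1) = dom;
    db += arma::sum(dom, 0);
  }
  dwm = colsT.t() * domAll;
  mat dcolsAll = domAll * wm.t();
  for (int n = 0; n < N; ++n) {
    mat dcolsT = dcolsAll.rows((size_t)n * HW, (size_t)(n + 1) * HW - 1);
    col2im_t(dcolsT, H, W, C, k, pad, dxv.begin() + (size_t)n * HW * C);
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(NumericVector x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("maxpool2 requires even spatial dimensions");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N);  // linear index into x
  const double* px = x.begin();
  double* po = out.begin();
  int* pi = idx.begin();
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++q) {
          const size_t i0 = base + (size_t)(2 * j) * H + 2 * i;
          size_t best = i0;
          double v = px[i0];
          if (px[i0 + 1] > v) { v = px[i0 + 1]; best = i0 + 1; }
          if (px[i0 + H] > v) { v = px[i0 + H]; best = i0 + H; }
          if (px[i0 + H + 1] > v) { v = px[i0 + H + 1]; best = i0 + H + 1; }
          po[q] = v;
          pi[q] = (int)best;
        }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
NumericVector maxpool2_bw(NumericVector dout, IntegerVector idx,
                          IntegerVector in_dim) {
  NumericVector dx = alloc4(in_dim[0], in_dim[1], in_dim[2], in_dim[3]);
  const double* pd = dout.begin();
  const int* pi = idx.begin();
  double* px = dx.begin();
  const R_xlen_t n = dout.size();
  for (R_xlen_t q = 0; q < n; ++q) px[pi[q]] += pd[q];
  return dx;
}

// Bilinear resampling by a factor of 1/2 (sampling at cell centres, which for
// an exact factor of two reduces to 2x2 block averaging); adjoint for backprop.
// [[Rcpp::export(name = ".avgdown2_fw")]]
NumericVector avgdown2_fw(NumericVector x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("downsample requires even spatial dimensions");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out = alloc4(Ho, Wo, C, N);
  const double* px = x.begin();
  double* po = out.begin();
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++q) {
          const size_t i0 = base + (size_t)(2 * j) * H + 2 * i;
          po[q] = 0.25 * (px[i0] + px[i0 + 1] + px[i0 + H] + px[i0 + H + 1]);
        }
    }
  return out;
}

// [[Rcpp::export(name = ".avgdown2_bw")]]
NumericVector avgdown2_bw(NumericVector dout) {
  IntegerVector d = dims4(dout);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  const int H = Ho * 2, W = Wo * 2;
  NumericVector dx = alloc4(H, W, C, N);
  const double* pd = dout.begin();
  double* px = dx.begin();
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++q) {
          const size_t i0 = base + (size_t)(2 * j) * H + 2 * i;
          const double g = 0.25 * pd[q];
          px[i0] += g; px[i0 + 1] += g; px[i0 + H] += g; px[i0 + H + 1] += g;
        }
    }
  return dx;
}
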