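// Convolution engine: im2col/col2im with dilation + GEMM, and max-pooling.
// Tensors are arma::cube [H, W, C]; patch rows are ordered ki + kj*kh + c*kh*kw,
// output positions are column-major (l = oi + oj*oH).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int out_size(int in, int k, int stride, int pad, int dil) {
  int keff = dil * (k - 1) + 1;
  return (in - keff + 2 * pad) / stride + 1;
}

// [[Rcpp::export]]
arma::mat ms_im2col(const arma::cube& x, int kh, int kw,
                    int stride, int pad_h, int pad_w, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oH = out_size(H, kh, stride, pad_h, dil);
  const int oW = out_size(W, kw, stride, pad_w, dil);
  mat cols(kh * kw * C, (uword)oH * oW, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kj * kh + c * kh * kw;
        for (int oj = 0; oj < oW; ++oj) {
          const int jj = oj * stride - pad_w + kj * dil;
          if (jj < 0 || jj >= W) continue;
          for (int oi = 0; oi < oH; ++oi) {
            const int ii = oi * stride - pad_h + ki * dil;
            if (ii < 0 || ii >= H) continue;
            cols(r, (uword)oi + (uword)oj * oH) = x(ii, jj, c);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::cube ms_col2im(const arma::mat& cols, int H, int W, int C,
                     int kh, int kw, int stride, int pad_h, int pad_w, int dil) {
  const int oH = out_size(H, kh, stride, pad_h, dil);
  const int oW = out_size(W, kw, stride, pad_w, dil);
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kj * kh + c * kh * kw;
        for (int oj = 0; oj < oW; ++oj) {
          const int jj = oj * stride - pad_w + kj * dil;
          if (jj < 0 || jj >= W) continue;
          for (int oi = 0; oi < oH; ++oi) {
            const int ii = oi * stride - pad_h + ki * dil;
            if (ii < 0 || ii >= H) continue;
            x(ii, jj, c) += cols(r, (uword)oi + (uword)oj * oH);
          }
        }
      }
    }
  }
  return x;
}

// Forward convolution: weight is [kh*kw*Cin, Cout], bias length Cout.
// [[Rcpp::export]]
arma::cube ms_conv_fwd(const arma::cube& x, const arma::mat& weight,
                       const arma::vec& bias, int kh, int kw,
                       int stride, int pad_h, int pad_w, int dil) {
  const int oH = out_size(x.n_rows, kh, stride, pad_h, dil);
  const int oW = out_size(x.n_cols, kw, stride, pad_w, dil);
  const int Cout = weight.n_cols;
  mat cols = ms_im2col(x, kh, kw, stride, pad_h, pad_w, dil);
  mat out = cols.t() * weight;            // [L, Cout]
  out.each_row() += bias.t();
  cube y(out.memptr(), oH, oW, Cout);
  return y;
}

// Backward convolution: returns dx, dW, db given upstream grad dy.
// [[Rcpp::export]]
Rcpp::List ms_conv_bwd(const arma::cube& x, const arma::cube& dy,
                       const arma::mat& weight, int kh, int kw,
                       int stride, int pad_h, int pad_w, int dil) {
  const int L = dy.n_rows * dy.n_cols;
  const int Cout = dy.n_slices;
  mat dy_flat(const_cast<double*>(dy.memptr()), L, Cout, false, true);
  mat cols = ms_im2col(x, kh, kw, stride, pad_h, pad_w, dil);
  mat dW = cols * dy_flat;                            // [k*Cin, Cout]
  vec db = sum(dy_flat, 0).t();
  mat dcols = weight * dy_flat.t();                   // [k*Cin, L]
  cube dx = ms_col2im(dcols, x.n_rows, x.n_cols, x.n_slices,
                      kh, kw, stride, pad_h, pad_w, dil);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Transposed convolution (adjoint of a conv mapping [oH,oW,Cout] -> [h,w,Cin]).
// weight is [kh*kw*Cout, Cin]; output size passed explicitly (output-size
// targeting resolves the stride-2 ambiguity: oH = stride*h for our stacks).
// [[Rcpp::export]]
arma::cube ms_tconv_fwd(const arma::cube& x, const arma::mat& weight,
                        const arma::vec& bias, int kh, int kw,
                        int stride, int pad, int oH, int oW) {
  const int L = x.n_rows * x.n_cols;
  const int Cin = x.n_slices;
  const int Cout = weight.n_rows / (kh * kw);
  mat x_flat(const_cast<double*>(x.memptr()), L, Cin, false, true);
  mat cols = weight * x_flat.t();                     // [k*Cout, L]
  cube y = ms_col2im(cols, oH, oW, Cout, kh, kw, stride, pad, pad, 1);
  for (int c = 0; c < Cout; ++c) y.slice(c) += bias(c);
  return y;
}

// [[Rcpp::export]]
Rcpp::List ms_tconv_bwd(const arma::cube& x, const arma::cube& dy,
                        const arma::mat& weight, int kh, int kw,
                        int stride, int pad) {
  const int L = x.n_rows * x.n_cols;
  const int Cin = x.n_slices;
  mat x_flat(const_cast<double*>(x.memptr()), L, Cin, false, true);
  mat dcols = ms_im2col(dy, kh, kw, stride, pad, pad, 1);  // [k*Cout, L]
  mat dx_flat = dcols.t() * weight;                   // [L, Cin]
  mat dW = dcols * x_flat;                            // [k*Cout, Cin]
  vec db(dy.n_slices);
  for (uword c = 0; c < dy.n_slices; ++c) db(c) = accu(dy.slice(c));
  cube dx(dx_flat.memptr(), x.n_rows, x.n_cols, Cin);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Max pooling, padding only on the bottom/right with -Inf (size-preserving
// when stride 1, pad k-1... callers pass pad in pixels appended per axis).
// Returns the pooled cube and 1-based linear argmax indices for backprop.
// [[Rcpp::export]]
Rcpp::List ms_maxpool_fwd(const arma::cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oH = (H + pad - k) / stride + 1;
  const int oW = (W + pad - k) / stride + 1;
  cube y(oH, oW, C);
  ucube idx(oH, oW, C);
  for (int c = 0; c < C; ++c) {
    for (int oj = 0; oj < oW; ++oj) {
      for (int oi = 0; oi < oH; ++oi) {
        double best = -datum::inf;
        uword best_lin = 0;
        for (int kj = 0; kj < k; ++kj) {
          const int jj = oj * stride + kj;
          if (jj >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int ii = oi * stride + ki;
            if (ii >= H) continue;
            const double v = x(ii, jj, c);
            if (v > best) {
              best = v;
              best_lin = (uword)ii + (uword)jj * H + (uword)c * H * W;
            }
          }
        }
        y(oi, oj, c) = best;
        idx(oi, oj, c) = best_lin + 1;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = y,
                            Rcpp::Named("argmax") = idx);
}

// [[Rcpp::export]]
arma::cube ms_maxpool_bwd(const arma::cube& dy, const arma::ucube& argmax,
                          int H, int W, int C) {
  cube dx(H, W, C, fill::zeros);
  for (uword i = 0; i < dy.n_elem; ++i) dx(argmax(i) - 1) += dy(i);
  return dx;
}
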