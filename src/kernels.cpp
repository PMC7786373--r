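// Convolution, pooling and resampling kernels.
//
// Activation layouts (column-major, matching R arrays):
//   2D: (H, W, C, N)           weights: (k, k, Cin, Cout)
//   3D: (H, W, L, C, N)        weights: (k, k, k, Cin, Cout)
//
// Convolutions are implemented as im2col + GEMM.  The im2col row index runs
// (kh, kw[, kl], c) fastest-first so that a column-major reshape of the
// weight array to (k^d * Cin, Cout) lines up with the patch matrix.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_extent(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// ---------------------------------------------------------------- 2D conv

static void im2col2d(const double* x, int H, int W, int C,
                     int k, int stride, int pad, arma::mat& cols) {
  const int oH = out_extent(H, k, stride, pad);
  const int oW = out_extent(W, k, stride, pad);
  cols.zeros(k * k * C, oH * oW);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * (kw + k * c);
        for (int ow = 0; ow < oW; ++ow) {
          const int w = ow * stride + kw - pad;
          if (w < 0 || w >= W) continue;
          double* col = cols.colptr(0) + r; // stride over columns below
          for (int oh = 0; oh < oH; ++oh) {
            const int h = oh * stride + kh - pad;
            if (h < 0 || h >= H) continue;
            col[(size_t)(oh + oH * ow) * cols.n_rows] = xc[h + (size_t)H * w];
          }
        }
      }
    }
  }
}

static void col2im2d(const arma::mat& cols, int H, int W, int C,
                     int k, int stride, int pad, double* x) {
  const int oH = out_extent(H, k, stride, pad);
  const int oW = out_extent(W, k, stride, pad);
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * (kw + k * c);
        for (int ow = 0; ow < oW; ++ow) {
          const int w = ow * stride + kw - pad;
          if (w < 0 || w >= W) continue;
          for (int oh = 0; oh < oH; ++oh) {
            const int h = oh * stride + kh - pad;
            if (h < 0 || h >= H) continue;
            xc[h + (size_t)H * w] +=
              cols.at(r, (size_t)(oh + oH * ow));
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch (%d vs %d)", C, Cin);
  const int oH = out_extent(H, k, stride, pad);
  const int oW = out_extent(W, k, stride, pad);
  if (oH < 1 || oW < 1) stop("conv2d: input smaller than kernel");
  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false);
  NumericVector y(Dimension(IntegerVector::create(oH, oW, Cout, N)));
  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    im2col2d(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, cols);
    arma::mat yn(y.begin() + (size_t)n * oH * oW * Cout, oH * oW, Cout, false, true);
    yn = cols.t() * Wm;
    if (bias.isNotNull()) {
      NumericVector b(bias);
      yn.each_row() += arma::rowvec(b.begin(), Cout, false);
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, bool need_dx, bool need_db,
                    Nullable<NumericVector> dwbuf = R_NilValue) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int oH = yd[0], oW = yd[1];
  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * C, Cout, false);
  NumericVector dw;
  if (dwbuf.isNotNull()) {
    dw = NumericVector(dwbuf);
    std::fill(dw.begin(), dw.end(), 0.0);
  } else {
    dw = NumericVector(Dimension(IntegerVector::create(k, k, C, Cout)));
  }
  arma::mat dWm(dw.begin(), k * k * C, Cout, false, true);
  NumericVector dx;
  if (need_dx) dx = NumericVector(Dimension(IntegerVector::create(H, W, C, N)));
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat cols, dcols;
  for (int n = 0; n < N; ++n) {
    const arma::mat dYn(const_cast<double*>(dy.begin()) + (size_t)n * oH * oW * Cout,
                        oH * oW, Cout, false);
    im2col2d(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, cols);
    dWm += cols * dYn;
    if (need_db) db += arma::sum(dYn, 0).t();
    if (need_dx) {
      dcols = Wm * dYn.t();
      col2im2d(dcols, H, W, C, k, stride, pad,
               dx.begin() + (size_t)n * H * W * C);
    }
  }
  return List::create(_["dw"] = dw, _["dx"] = dx,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// ---------------------------------------------------------------- 3D conv

static void im2col3d(const double* x, int H, int W, int L, int C,
                     int k, int stride, int pad, arma::mat& cols) {
  const int oH = out_extent(H, k, stride, pad);
  const int oW = out_extent(W, k, stride, pad);
  const int oL = out_extent(L, k, stride, pad);
  cols.zeros((size_t)k * k * k * C, (size_t)oH * oW * oL);
  const size_t nr = cols.n_rows;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W * L;
    for (int kl = 0; kl < k; ++kl)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh) {
          const size_t r = kh + (size_t)k * (kw + (size_t)k * (kl + (size_t)k * c));
          for (int ol = 0; ol < oL; ++ol) {
            const int l = ol * stride + kl - pad;
            if (l < 0 || l >= L) continue;
            for (int ow = 0; ow < oW; ++ow) {
              const int w = ow * stride + kw - pad;
              if (w < 0 || w >= W) continue;
              const size_t jbase = (size_t)oH * (ow + (size_t)oW * ol);
              const size_t xbase = (size_t)H * (w + (size_t)W * l);
              for (int oh = 0; oh < oH; ++oh) {
                const int h = oh * stride + kh - pad;
                if (h < 0 || h >= H) continue;
                cols.memptr()[r + nr * (jbase + oh)] = xc[h + xbase];
              }
            }
          }
        }
  }
}

static void col2im3d(const arma::mat& cols, int H, int W, int L, int C,
                     int k, int stride, int pad, double* x) {
  const int oH = out_extent(H, k, stride, pad);
  const int oW = out_extent(W, k, stride, pad);
  const int oL = out_extent(L, k, stride, pad);
  const size_t nr = cols.n_rows;
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W * L;
    for (int kl = 0; kl < k; ++kl)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh) {
          const size_t r = kh + (size_t)k * (kw + (size_t)k * (kl + (size_t)k * c));
          for (int ol = 0; ol < oL; ++ol) {
            const int l = ol * stride + kl - pad;
            if (l < 0 || l >= L) continue;
            for (int ow = 0; ow < oW; ++ow) {
              const int w = ow * stride + kw - pad;
              if (w < 0 || w >= W) continue;
              const size_t jbase = (size_t)oH * (ow + (size_t)oW * ol);
              const size_t xbase = (size_t)H * (w + (size_t)W * l);
              for (int oh = 0; oh < oH; ++oh) {
                const int h = oh * stride + kh - pad;
                if (h < 0 || h >= H) continue;
                xc[h + xbase] += cols.memptr()[r + nr * (jbase + oh)];
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], L = xd[2], C = xd[3], N = xd[4];
  const int k = wd[0], Cin = wd[3], Cout = wd[4];
  if (Cin != C) stop("conv3d: channel mismatch (%d vs %d)", C, Cin);
  const int oH = out_extent(H, k, stride, pad);
  const int oW = out_extent(W, k, stride, pad);
  const int oL = out_extent(L, k, stride, pad);
  if (oH < 1 || oW < 1 || oL < 1) stop("conv3d: input smaller than kernel");
  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * k * Cin, Cout, false);
  NumericVector y(Dimension(IntegerVector::create(oH, oW, oL, Cout, N)));
  arma::mat cols;
  const size_t oHWL = (size_t)oH * oW * oL;
  for (int n = 0; n < N; ++n) {
    im2col3d(x.begin() + (size_t)n * H * W * L * C, H, W, L, C, k, stride, pad, cols);
    arma::mat yn(y.begin() + (size_t)n * oHWL * Cout, oHWL, Cout, false, true);
    yn = cols.t() * Wm;
    if (bias.isNotNull()) {
      NumericVector b(bias);
      yn.each_row() += arma::rowvec(b.begin(), Cout, false);
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, bool need_dx, bool need_db,
                    Nullable<NumericVector> dwbuf = R_NilValue) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], L = xd[2], C = xd[3], N = xd[4];
  const int k = wd[0], Cout = wd[4];
  const size_t oHWL = (size_t)yd[0] * yd[1] * yd[2];
  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * k * C, Cout, false);
  NumericVector dw;
  if (dwbuf.isNotNull()) {
    dw = NumericVector(dwbuf);
    std::fill(dw.begin(), dw.end(), 0.0);
  } else {
    dw = NumericVector(Dimension(IntegerVector::create(k, k, k, C, Cout)));
  }
  arma::mat dWm(dw.begin(), (size_t)k * k * k * C, Cout, false, true);
  NumericVector dx;
  if (need_dx) dx = NumericVector(Dimension(IntegerVector::create(H, W, L, C, N)));
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat cols, dcols;
  for (int n = 0; n < N; ++n) {
    const arma::mat dYn(const_cast<double*>(dy.begin()) + (size_t)n * oHWL * Cout,
                        oHWL, Cout, false);
    im2col3d(x.begin() + (size_t)n * H * W * L * C, H, W, L, C, k, stride, pad, cols);
    dWm += cols * dYn;
    if (need_db) db += arma::sum(dYn, 0).t();
    if (need_dx) {
      dcols = Wm * dYn.t();
      col2im3d(dcols, H, W, L, C, k, stride, pad,
               dx.begin() + (size_t)n * H * W * L * C);
    }
  }
  return List::create(_["dw"] = dw, _["dx"] = dx,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// ---------------------------------------------------------------- pooling

// [[Rcpp::export]]
List maxpool2d_fwd_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int oH = out_extent(H, k, stride, pad);
  const int oW = out_extent(W, k, stride, pad);
  NumericVector y(Dimension(IntegerVector::create(oH, oW, C, N)));
  IntegerVector idx(y.size()); // 0-based flat index into x of each max
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)(n * C + c) * H * W;
      for (int ow = 0; ow < oW; ++ow)
        for (int oh = 0; oh < oH; ++oh) {
          double best = -INFINITY; size_t bi = 0;
          for (int kw = 0; kw < k; ++kw) {
            const int w = ow * stride + kw - pad;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h = oh * stride + kh - pad;
              if (h < 0 || h >= H) continue;
              const size_t xi = base + h + (size_t)H * w;
              if (x[xi] > best) { best = x[xi]; bi = xi; }
            }
          }
          // y is filled in (oh, ow, c, n) order -> recompute position
          const size_t yi = (size_t)oh + (size_t)oH * (ow + (size_t)oW * (c + (size_t)C * n));
          y[yi] = best; idx[yi] = (int)bi;

        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(IntegerVector idx, NumericVector dy,
                              IntegerVector xdim) {
  size_t total = 1;
  for (int i = 0; i < xdim.size(); ++i) total *= (size_t)xdim[i];
  NumericVector dx((R_xlen_t)total);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// [[Rcpp::export]]
List maxpool3d_fwd_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], L = xd[2], C = xd[3], N = xd[4];
  const int oH = out_extent(H, k, stride, pad);
  const int oW = out_extent(W, k, stride, pad);
  const int oL = out_extent(L, k, stride, pad);
  NumericVector y(Dimension(IntegerVector::create(oH, oW, oL, C, N)));
  IntegerVector idx(y.size());
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)(n * C + c) * H * W * L;
      for (int ol = 0; ol < oL; ++ol)
        for (int ow = 0; ow < oW; ++ow)
          for (int oh = 0; oh < oH; ++oh) {
            double best = -INFINITY; size_t bi = 0;
            for (int kl = 0; kl < k; ++kl) {
              const int l = ol * stride + kl - pad;
              if (l < 0 || l >= L) continue;
              for (int kw = 0; kw < k; ++kw) {
                const int w = ow * stride + kw - pad;
                if (w < 0 || w >= W) continue;
                for (int kh = 0; kh < k; ++kh) {
                  const int h = oh * stride + kh - pad;
                  if (h < 0 || h >= H) continue;
                  const size_t xi = base + h + (size_t)H * (w + (size_t)W * l);
                  if (x[xi] > best) { best = x[xi]; bi = xi; }
                }
              }
            }
            const size_t yi = (size_t)oh + (size_t)oH *
              (ow + (size_t)oW * (ol + (size_t)oL * (c + (size_t)C * n)));
            y[yi] = best; idx[yi] = (int)bi;
          }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// ------------------------------------------------- in-place SGD update

// v <- momentum * v - lr * g ; p <- p + v   (all modified in place)
// [[Rcpp::export]]
void sgd_update_cpp(NumericVector p, NumericVector v, NumericVector g,
                    double lr, double momentum) {
  double* pp = p.begin(); double* vv = v.begin(); double* gg = g.begin();
  const R_xlen_t n = p.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    vv[i] = momentum * vv[i] - lr * gg[i];
    pp[i] += vv[i];
  }
}

// Zero a numeric buffer in place (gradient accumulators are reused
// across steps to avoid repeated large allocations).
// [[Rcpp::export]]
void zero_fill_cpp(NumericVector x) {
  std::fill(x.begin(), x.end(), 0.0);
}
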