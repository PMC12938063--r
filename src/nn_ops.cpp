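#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Layout conventions shared with the R side:
//  - feature maps are arma::cube H x W x C
//  - conv weights are matrices C_out x (C_in * k * k), flat kernel index
//    c * k * k + ki * k + kj (0-based), ki along rows (H), kj along cols (W)
//  - "same" zero padding; dilation d spaces kernel taps d pixels apart, so
//    the effective receptive field of one layer is (k - 1) * d + 1

static arma::mat im2col_dilated(const arma::cube& x, int k, int d) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = ((k - 1) * d) / 2;
  arma::mat cols(C * k * k, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int r = c * k * k + ki * k + kj;
        const int di = ki * d - pad, dj = kj * d - pad;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di;
            if (si < 0 || si >= H) continue;
            cols(r, j * H + i) = x(si, sj, c);
          }
        }
      }
    }
  }
  return cols;
}

// scatter-add the column matrix back onto an image (adjoint of im2col)
static arma::cube col2im_dilated(const arma::mat& cols, int H, int W, int C,
                                 int k, int d) {
  const int pad = ((k - 1) * d) / 2;
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int r = c * k * k + ki * k + kj;
        const int di = ki * d - pad, dj = kj * d - pad;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di;
            if (si < 0 || si >= H) continue;
            x(si, sj, c) += cols(r, j * H + i);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_forward(const arma::cube& x, const arma::mat& w,
                              const arma::vec& b, int k, int d) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_rows;
  arma::mat cols = im2col_dilated(x, k, d);
  arma::mat out = w * cols;               // Cout x (H*W)
  out.each_col() += b;
  arma::cube y(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    y.slice(c) = arma::reshape(out.row(c), H, W);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(const arma::cube& x, const arma::mat& w,
                         const arma::cube& gy, int k, int d) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_rows;
  arma::mat gmat(Cout, H * W);
  for (int c = 0; c < Cout; ++c)
    gmat.row(c) = arma::vectorise(gy.slice(c)).t();
  arma::mat cols = im2col_dilated(x, k, d);
  arma::mat gw = gmat * cols.t();
  arma::vec gb = arma::sum(gmat, 1);
  arma::mat gcols = w.t() * gmat;
  arma::cube gx = col2im_dilated(gcols, H, W, Cin, k, d);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2; H and W must be even.  idx stores, per output
// pixel and channel, the 0-based linear index (within the slice) of the max.
// [[Rcpp::export]]
List cpp_maxpool2_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int si = 2 * i + di, sj = 2 * j + dj;
            const double v = x(si, sj, c);
            if (v > best) { best = v; bi = (arma::uword)(sj * H + si); }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_backward(const arma::cube& gy, const arma::ucube& idx,
                                 int H, int W) {
  const int C = gy.n_slices, Ho = gy.n_rows, Wo = gy.n_cols;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        gx.slice(c)(idx(i, j, c)) += gy(i, j, c);
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_backward(const arma::cube& gy) {
  const int H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  arma::cube gx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        gx(i, j, c) = gy(2 * i, 2 * j, c) + gy(2 * i + 1, 2 * j, c) +
                      gy(2 * i, 2 * j + 1, c) + gy(2 * i + 1, 2 * j + 1, c);
  return gx;
}
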