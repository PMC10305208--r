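// Low-level layer primitives for the five-level U-Net: 3x3 same-padding
// convolution, 2x2 max pooling, and 3x3 stride-2 transposed convolution,
// each with the adjoint (backward) pass used by backpropagation.
//
// Layout conventions shared with the R side:
//   * feature maps are H x W x C arrays (R array == arma::cube, column-major)
//   * conv weights:   (9*Cin) x Cout matrix, row index = cin*9 + b*3 + a
//                     where (a, b) is the kernel (row, col) offset in 0..2
//   * up-conv weights: Cin x (9*Cout) matrix, col index = cout*9 + b*3 + a
// so that both directions reduce to one GEMM plus a gather/scatter.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col for a 3x3 kernel, zero padding 1, stride 1.
// Returns (H*W) x (9*C); column c*9 + b*3 + a holds x(i+a-1, j+b-1, c).
static arma::mat im2col3(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat M(H * W, 9 * C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    const arma::mat& s = x.slice(c);
    for (int b = 0; b < 3; ++b) {
      for (int a = 0; a < 3; ++a) {
        const arma::uword col = c * 9 + b * 3 + a;
        // output pixel (i, j) reads s(i + a - 1, j + b - 1)
        const arma::uword ilo = (a == 0) ? 1 : 0;
        const arma::uword ihi = (a == 2) ? H - 2 : H - 1;
        const arma::uword jlo = (b == 0) ? 1 : 0;
        const arma::uword jhi = (b == 2) ? W - 2 : W - 1;
        arma::mat Mv(M.colptr(col), H, W, false, true);
        Mv.submat(ilo, jlo, ihi, jhi) =
          s.submat(ilo + a - 1, jlo + b - 1, ihi + a - 1, jhi + b - 1);
      }
    }
  }
  return M;
}

// Adjoint of im2col3: scatter-add columns of M back onto an H x W x C cube.
static arma::cube col2im3(const arma::mat& M, arma::uword H, arma::uword W,
                          arma::uword C) {
  arma::cube g(H, W, C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    arma::mat& gs = g.slice(c);
    for (int b = 0; b < 3; ++b) {
      for (int a = 0; a < 3; ++a) {
        const arma::uword col = c * 9 + b * 3 + a;
        const arma::uword ilo = (a == 0) ? 1 : 0;
        const arma::uword ihi = (a == 2) ? H - 2 : H - 1;
        const arma::uword jlo = (b == 0) ? 1 : 0;
        const arma::uword jhi = (b == 2) ? W - 2 : W - 1;
        const arma::mat Mv(const_cast<double*>(M.colptr(col)), H, W, false,
                           true);
        gs.submat(ilo + a - 1, jlo + b - 1, ihi + a - 1, jhi + b - 1) +=
          Mv.submat(ilo, jlo, ihi, jhi);
      }
    }
  }
  return g;
}

// [[Rcpp::export(name = ".conv3_forward")]]
arma::cube conv3_forward(const arma::cube& x, const arma::mat& W,
                         const arma::vec& b) {
  const arma::uword H = x.n_rows, Wd = x.n_cols;
  const arma::uword F = W.n_cols;
  arma::mat out = im2col3(x) * W;      // (H*W) x F
  out.each_row() += b.t();
  arma::cube y(H, Wd, F);
  std::memcpy(y.memptr(), out.memptr(), sizeof(double) * out.n_elem);
  return y;
}

// [[Rcpp::export(name = ".conv3_backward")]]
List conv3_backward(const arma::cube& x, const arma::mat& W,
                    const arma::cube& gout) {
  const arma::uword H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const arma::uword F = gout.n_slices;
  const arma::mat G(const_cast<double*>(gout.memptr()), H * Wd, F, false,
                    true);
  arma::mat M = im2col3(x);
  arma::mat gW = M.t() * G;
  arma::vec gb = arma::sum(G, 0).t();
  arma::cube gx = col2im3(G * W.t(), H, Wd, C);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Also returns 1-based linear argmax indices
// into x so the backward pass is a pure scatter.
// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const arma::uword Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  IntegerVector idx(Ho * Wo * C);
  for (arma::uword c = 0; c < C; ++c) {
    const arma::mat& s = x.slice(c);
    for (arma::uword j = 0; j < Wo; ++j) {
      for (arma::uword i = 0; i < Ho; ++i) {
        arma::uword bi = 2 * i, bj = 2 * j, mi = bi, mj = bj;
        double m = s(bi, bj);
        if (s(bi + 1, bj) > m)     { m = s(bi + 1, bj);     mi = bi + 1; mj = bj;     }
        if (s(bi, bj + 1) > m)     { m = s(bi, bj + 1);     mi = bi;     mj = bj + 1; }
        if (s(bi + 1, bj + 1) > m) { m = s(bi + 1, bj + 1); mi = bi + 1; mj = bj + 1; }
        y(i, j, c) = m;
        idx[c * Ho * Wo + j * Ho + i] =
          static_cast<int>(c * H * W + mj * H + mi + 1);
      }
    }
  }
  return List::create(_["out"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
arma::cube maxpool2_backward(const IntegerVector& idx, const arma::cube& gout,
                             int H, int W) {
  const arma::uword C = gout.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  const double* g = gout.memptr();
  for (arma::uword k = 0; k < gout.n_elem; ++k)
    gx(static_cast<arma::uword>(idx[k] - 1)) += g[k];
  return gx;
}

// Transposed convolution, 3x3 kernel, stride 2, padding 1, output padding 1:
// an H x W x Cin map becomes 2H x 2W x F. Input pixel (i, j) with kernel
// offset (a, b) contributes to output pixel (2i + a - 1, 2j + b - 1).
// [[Rcpp::export(name = ".upconv2_forward")]]
arma::cube upconv2_forward(const arma::cube& x, const arma::mat& W,
                           const arma::vec& b) {
  const arma::uword H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const arma::uword F = W.n_cols / 9;
  const arma::uword Ho = 2 * H, Wo = 2 * Wd;
  const arma::mat X(const_cast<double*>(x.memptr()), H * Wd, C, false, true);
  arma::mat Y = X * W;                 // (H*W) x (9*F)
  arma::cube y(Ho, Wo, F, arma::fill::zeros);
  for (arma::uword f = 0; f < F; ++f) {
    arma::mat& ys = y.slice(f);
    for (int bb = 0; bb < 3; ++bb) {
      for (int aa = 0; aa < 3; ++aa) {
        const arma::mat Yv(const_cast<double*>(Y.colptr(f * 9 + bb * 3 + aa)),
                           H, Wd, false, true);
        for (arma::uword j = 0; j < Wd; ++j) {
          const long s = 2 * static_cast<long>(j) + bb - 1;
          if (s < 0 || s >= static_cast<long>(Wo)) continue;
          for (arma::uword i = 0; i < H; ++i) {
            const long r = 2 * static_cast<long>(i) + aa - 1;
            if (r < 0 || r >= static_cast<long>(Ho)) continue;
            ys(static_cast<arma::uword>(r), static_cast<arma::uword>(s)) +=
              Yv(i, j);
          }
        }
      }
    }
    ys += b(f);
  }
  return y;
}

// [[Rcpp::export(name = ".upconv2_backward")]]
List upconv2_backward(const arma::cube& x, const arma::mat& W,
                      const arma::cube& gout) {
  const arma::uword H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const arma::uword F = gout.n_slices;
  const arma::uword Ho = gout.n_rows, Wo = gout.n_cols;
  arma::mat gY(H * Wd, 9 * F, arma::fill::zeros);
  for (arma::uword f = 0; f < F; ++f) {
    const arma::mat& gs = gout.slice(f);
    for (int bb = 0; bb < 3; ++bb) {
      for (int aa = 0; aa < 3; ++aa) {
        arma::mat gYv(gY.colptr(f * 9 + bb * 3 + aa), H, Wd, false, true);
        for (arma::uword j = 0; j < Wd; ++j) {
          const long s = 2 * static_cast<long>(j) + bb - 1;
          if (s < 0 || s >= static_cast<long>(Wo)) continue;
          for (arma::uword i = 0; i < H; ++i) {
            const long r = 2 * static_cast<long>(i) + aa - 1;
            if (r < 0 || r >= static_cast<long>(Ho)) continue;
            gYv(i, j) = gs(static_cast<arma::uword>(r),
                           static_cast<arma::uword>(s));
          }
        }
      }
    }
  }
  const arma::mat X(const_cast<double*>(x.memptr()), H * Wd, C, false, true);
  arma::mat gW = X.t() * gY;
  arma::vec gb(F);
  for (arma::uword f = 0; f < F; ++f) gb(f) = arma::accu(gout.slice(f));
  arma::mat gXm = gY * W.t();
  arma::cube gx(H, Wd, C);
  std::memcpy(gx.memptr(), gXm.memptr(), sizeof(double) * gXm.n_elem);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}
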