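// Low-level layer kernels for the encoder-decoder segmentation network.
// Activations are (H, W, C) cubes in R's column-major pixel order; 3x3
// convolutions use same-padding im2col + BLAS GEMM, with direct pointer
// copies to keep the im2col/col2im overhead below the GEMM cost.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for a 3x3 kernel with zero padding 1.
// Returns (H*W) x (9*C); column index r = di + 3*dj + 9*ci matches the
// column-major flattening of a (3, 3, Cin, Cout) weight array.
static void im2col3(const cube &X, mat &K) {
  const uword H = X.n_rows, W = X.n_cols, C = X.n_slices;
  K.set_size(H * W, 9 * C);
  mat pad(H + 2, W + 2);
  for (uword c = 0; c < C; ++c) {
    pad.zeros();
    pad.submat(1, 1, H, W) = X.slice(c);
    for (uword dj = 0; dj < 3; ++dj) {
      for (uword di = 0; di < 3; ++di) {
        double *dst = K.colptr(di + 3 * dj + 9 * c);
        for (uword j = 0; j < W; ++j) {
          std::memcpy(dst + j * H, pad.colptr(dj + j) + di,
                      H * sizeof(double));
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv3_fwd(const arma::cube &X, const arma::mat &Wm,
                     const arma::vec &b) {
  const uword H = X.n_rows, W = X.n_cols, Cout = Wm.n_cols;
  mat K;
  im2col3(X, K);
  cube Y(H, W, Cout);
  mat Ym(Y.memptr(), H * W, Cout, false, true);
  Ym = K * Wm;
  Ym.each_row() += b.t();
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv3_bwd(const arma::cube &X, const arma::mat &Wm,
                     const arma::cube &dY, bool need_dx = true) {
  const uword H = X.n_rows, W = X.n_cols, Cin = X.n_slices;
  const uword Cout = dY.n_slices;
  mat dYm(const_cast<double *>(dY.memptr()), H * W, Cout, false, true);
  mat K;
  im2col3(X, K);
  mat dW = K.t() * dYm;          // (9 Cin) x Cout
  vec db = sum(dYm, 0).t();
  if (!need_dx) {
    return Rcpp::List::create(Rcpp::Named("dX") = R_NilValue,
                              Rcpp::Named("dW") = dW, Rcpp::Named("db") = db);
  }
  // dX as a correlation of dY with the 180-degree-rotated kernel:
  // dX[:, ci] = im2col3(dY) * Wrot[:, ci], avoiding a scatter-add.
  mat KdY;
  im2col3(dY, KdY);              // (HW) x (9 Cout)
  mat Wrot(9 * Cout, Cin);
  for (uword co = 0; co < Cout; ++co) {
    for (uword dj = 0; dj < 3; ++dj) {
      for (uword di = 0; di < 3; ++di) {
        const uword r = di + 3 * dj + 9 * co;
        const uword s = (2 - di) + 3 * (2 - dj);
        for (uword ci = 0; ci < Cin; ++ci) {
          Wrot(r, ci) = Wm(s + 9 * ci, co);
        }
      }
    }
  }
  cube dX(H, W, Cin);
  mat dXm(dX.memptr(), H * W, Cin, false, true);
  dXm = KdY * Wrot;
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
arma::cube conv1_fwd(const arma::cube &X, const arma::mat &Wm,
                     const arma::vec &b) {
  const uword H = X.n_rows, W = X.n_cols, Cin = X.n_slices;
  mat Xm(const_cast<double *>(X.memptr()), H * W, Cin, false, true);
  cube Y(H, W, Wm.n_cols);
  mat Ym(Y.memptr(), H * W, Wm.n_cols, false, true);
  Ym = Xm * Wm;
  Ym.each_row() += b.t();
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv1_bwd(const arma::cube &X, const arma::mat &Wm,
                     const arma::cube &dY) {
  const uword H = X.n_rows, W = X.n_cols, Cin = X.n_slices;
  mat Xm(const_cast<double *>(X.memptr()), H * W, Cin, false, true);
  mat dYm(const_cast<double *>(dY.memptr()), H * W, dY.n_slices, false, true);
  mat dW = Xm.t() * dYm;
  vec db = sum(dYm, 0).t();
  cube dX(H, W, Cin);
  mat dXm(dX.memptr(), H * W, Cin, false, true);
  dXm = dYm * Wm.t();
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Per-channel sums and sums of squares (for batch-norm moments).
// [[Rcpp::export]]
arma::mat bn_moments(const arma::cube &X) {
  const uword C = X.n_slices;
  mat out(C, 2);
  for (uword c = 0; c < C; ++c) {
    const double *p = X.slice_memptr(c);
    double s = 0, ss = 0;
    const uword n = X.n_rows * X.n_cols;
    for (uword k = 0; k < n; ++k) { s += p[k]; ss += p[k] * p[k]; }
    out(c, 0) = s;
    out(c, 1) = ss;
  }
  return out;
}

// Fused batch-norm + ReLU forward for one sample:
// xhat = (Z - mu) * istd;  A = max(0, gamma * xhat + beta).
// [[Rcpp::export]]
Rcpp::List bnrelu_fwd(const arma::cube &Z, const arma::vec &mu,
                      const arma::vec &istd, const arma::vec &gamma,
                      const arma::vec &beta) {
  const uword H = Z.n_rows, W = Z.n_cols, C = Z.n_slices;
  cube xhat(H, W, C), A(H, W, C);
  const uword n = H * W;
  for (uword c = 0; c < C; ++c) {
    const double *z = Z.slice_memptr(c);
    double *xh = xhat.slice_memptr(c);
    double *a = A.slice_memptr(c);
    const double m = mu(c), is = istd(c), g = gamma(c), bb = beta(c);
    for (uword k = 0; k < n; ++k) {
      const double x = (z[k] - m) * is;
      xh[k] = x;
      const double y = g * x + bb;
      a[k] = y > 0 ? y : 0;
    }
  }
  return Rcpp::List::create(Rcpp::Named("xhat") = xhat, Rcpp::Named("A") = A);
}

// First backward pass of fused BN+ReLU: per-channel sums of
// dY = dA * 1[A > 0] and dY * xhat. Returns (C x 2): [sum_dY, sum_dY_xhat].
// [[Rcpp::export]]
arma::mat bnrelu_bwd_sums(const arma::cube &dA, const arma::cube &A,
                          const arma::cube &xhat) {
  const uword C = dA.n_slices, n = dA.n_rows * dA.n_cols;
  mat out(C, 2);
  for (uword c = 0; c < C; ++c) {
    const double *da = dA.slice_memptr(c);
    const double *a = A.slice_memptr(c);
    const double *xh = xhat.slice_memptr(c);
    double s = 0, sx = 0;
    for (uword k = 0; k < n; ++k) {
      if (a[k] > 0) { s += da[k]; sx += da[k] * xh[k]; }
    }
    out(c, 0) = s;
    out(c, 1) = sx;
  }
  return out;
}

// Second backward pass: dZ = istd * (gamma * dY - mean_dxhat
//                                    - xhat * mean_dxhat_xhat)
// with dY = dA * 1[A > 0]; the mean_* vectors are batch means of
// gamma * dY and gamma * dY * xhat (training mode), or zero (inference
// statistics).
// [[Rcpp::export]]
arma::cube bnrelu_bwd(const arma::cube &dA, const arma::cube &A,
                      const arma::cube &xhat, const arma::vec &gamma,
                      const arma::vec &istd, const arma::vec &mean_dxhat,
                      const arma::vec &mean_dxhat_xhat) {
  const uword H = dA.n_rows, W = dA.n_cols, C = dA.n_slices;
  cube dZ(H, W, C);
  const uword n = H * W;
  for (uword c = 0; c < C; ++c) {
    const double *da = dA.slice_memptr(c);
    const double *a = A.slice_memptr(c);
    const double *xh = xhat.slice_memptr(c);
    double *dz = dZ.slice_memptr(c);
    const double g = gamma(c), is = istd(c);
    const double md = mean_dxhat(c), mdx = mean_dxhat_xhat(c);
    for (uword k = 0; k < n; ++k) {
      const double dy = a[k] > 0 ? da[k] : 0;
      dz[k] = is * (g * dy - md - xh[k] * mdx);
    }
  }
  return dZ;
}

// 2x2 max-pooling, stride 2, with 1-based linear argmax indices.
// [[Rcpp::export]]
Rcpp::List pool2_fwd(const arma::cube &X) {
  const uword H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const uword Ho = H / 2, Wo = W / 2;
  cube Y(Ho, Wo, C);
  ucube idx(Ho, Wo, C);
  for (uword c = 0; c < C; ++c) {
    for (uword j = 0; j < Wo; ++j) {
      for (uword i = 0; i < Ho; ++i) {
        uword bi = 2 * i, bj = 2 * j, ai = bi, aj = bj;
        double best = X(bi, bj, c);
        if (X(bi + 1, bj, c) > best) { best = X(bi + 1, bj, c); ai = bi + 1; }
        if (X(bi, bj + 1, c) > best) { best = X(bi, bj + 1, c); ai = bi; aj = bj + 1; }
        if (X(bi + 1, bj + 1, c) > best) { best = X(bi + 1, bj + 1, c); ai = bi + 1; aj = bj + 1; }
        Y(i, j, c) = best;
        idx(i, j, c) = ai + H * aj + H * W * c + 1;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube pool2_bwd(const arma::cube &dY, const arma::ucube &idx,
                     int H, int W) {
  const uword C = dY.n_slices;
  cube dX((uword)H, (uword)W, C, fill::zeros);
  const uword n = dY.n_elem;
  for (uword k = 0; k < n; ++k) dX(idx(k) - 1) += dY(k);
  return dX;
}

// Transpose convolution, 2x2 kernel, stride 2 (exact 2x upsampling).
// Wm is (4*Cin) x Cout, row index = di + 2*dj + 4*ci (column-major
// flattening of a (2, 2, Cin, Cout) array).
// [[Rcpp::export]]
arma::cube tconv2_fwd(const arma::cube &X, const arma::mat &Wm,
                      const arma::vec &b) {
  const uword H = X.n_rows, W = X.n_cols, Cin = X.n_slices;
  const uword Cout = Wm.n_cols;
  mat Xm(const_cast<double *>(X.memptr()), H * W, Cin, false, true);
  cube Y(2 * H, 2 * W, Cout);
  for (uword co = 0; co < Cout; ++co) Y.slice(co).fill(b(co));
  mat Wsub(Cin, Cout);
  for (uword dj = 0; dj < 2; ++dj) {
    for (uword di = 0; di < 2; ++di) {
      for (uword ci = 0; ci < Cin; ++ci)
        Wsub.row(ci) = Wm.row(di + 2 * dj + 4 * ci);
      mat Ys = Xm * Wsub;  // (HW) x Cout
      for (uword co = 0; co < Cout; ++co) {
        const double *src = Ys.colptr(co);
        for (uword j = 0; j < W; ++j) {
          double *dst = Y.slice_memptr(co) + (2 * j + dj) * 2 * H + di;
          const double *s = src + j * H;
          for (uword i = 0; i < H; ++i) dst[2 * i] += s[i];
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List tconv2_bwd(const arma::cube &X, const arma::mat &Wm,
                      const arma::cube &dY) {
  const uword H = X.n_rows, W = X.n_cols, Cin = X.n_slices;
  const uword Cout = dY.n_slices;
  mat Xm(const_cast<double *>(X.memptr()), H * W, Cin, false, true);
  mat dW(4 * Cin, Cout, fill::zeros);
  vec db(Cout);
  for (uword co = 0; co < Cout; ++co) db(co) = accu(dY.slice(co));
  cube dX(H, W, Cin, fill::zeros);
  mat dXm(dX.memptr(), H * W, Cin, false, true);
  mat dYs(H * W, Cout);
  mat Wsub(Cin, Cout);
  for (uword dj = 0; dj < 2; ++dj) {
    for (uword di = 0; di < 2; ++di) {
      for (uword co = 0; co < Cout; ++co) {
        double *dst = dYs.colptr(co);
        const double *sl = dY.slice_memptr(co);
        for (uword j = 0; j < W; ++j) {
          const double *s = sl + (2 * j + dj) * 2 * H + di;
          double *d = dst + j * H;
          for (uword i = 0; i < H; ++i) d[i] = s[2 * i];
        }
      }
      mat dWsub = Xm.t() * dYs;  // Cin x Cout
      for (uword ci = 0; ci < Cin; ++ci)
        dW.row(di + 2 * dj + 4 * ci) = dWsub.row(ci);
      for (uword ci = 0; ci < Cin; ++ci)
        Wsub.row(ci) = Wm.row(di + 2 * dj + 4 * ci);
      dXm += dYs * Wsub.t();
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
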