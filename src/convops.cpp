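// Minimal conv-net primitives for the tiny desk-scale backbones.
//
// A batch of S slice feature maps travels as an arma::cube of dimensions
// H x W x (C*S): the R array dim c(H, W, C, S) reinterpreted with the
// channel blocks of each slice contiguous.  Convolutions are 3x3, stride
// 1, zero "same" padding; the weight matrix is (9*Cin) x Cout with column
// index  c*9 + (dj+1)*3 + (di+1)  for spatial offset (di, dj).  The
// pooling ops act per 2-D plane and are agnostic to the channel/slice
// grouping.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// fill P (H*W x 9*C, pre-zeroed) with patches of channels [c0, c0+C) of X
static void im2col3x3(const arma::cube& X, arma::uword c0, arma::uword C,
                      arma::mat& P) {
  const arma::uword H = X.n_rows, W = X.n_cols;
  for (arma::uword c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const arma::uword col = c * 9 + (dj + 1) * 3 + (di + 1);
        for (arma::uword j = 0; j < W; ++j) {
          const int jj = (int)j + dj;
          if (jj < 0 || jj >= (int)W) continue;
          for (arma::uword i = 0; i < H; ++i) {
            const int ii = (int)i + di;
            if (ii < 0 || ii >= (int)H) continue;
            P(i + j * H, col) = X(ii, jj, c0 + c);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv3x3_fwd(const arma::cube& X, int cin, const arma::mat& W,
                           const arma::vec& b) {
  const arma::uword H = X.n_rows, Wd = X.n_cols;
  const arma::uword C = (arma::uword)cin;
  const arma::uword S = X.n_slices / C;
  const arma::uword Cout = W.n_cols;
  arma::cube out(H, Wd, Cout * S);
  arma::mat P(H * Wd, 9 * C);
  for (arma::uword s = 0; s < S; ++s) {
    P.zeros();
    im2col3x3(X, s * C, C, P);
    arma::mat Y = P * W;
    Y.each_row() += b.t();
    for (arma::uword k = 0; k < Cout; ++k)
      out.slice(s * Cout + k) = arma::reshape(Y.col(k), H, Wd);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3x3_bwd(const arma::cube& X, int cin, const arma::mat& W,
                     const arma::cube& dY) {
  const arma::uword H = X.n_rows, Wd = X.n_cols;
  const arma::uword C = (arma::uword)cin;
  const arma::uword S = X.n_slices / C;
  const arma::uword Cout = W.n_cols;
  arma::mat dW(arma::size(W), arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::cube dX(H, Wd, C * S, arma::fill::zeros);
  arma::mat P(H * Wd, 9 * C);
  arma::mat dYm(H * Wd, Cout);
  for (arma::uword s = 0; s < S; ++s) {
    P.zeros();
    im2col3x3(X, s * C, C, P);
    for (arma::uword k = 0; k < Cout; ++k)
      dYm.col(k) = arma::vectorise(dY.slice(s * Cout + k));
    dW += P.t() * dYm;
    db += arma::sum(dYm, 0).t();
    arma::mat dP = dYm * W.t();
    // scatter-add dP back through the same patch mapping
    for (arma::uword c = 0; c < C; ++c) {
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const arma::uword col = c * 9 + (dj + 1) * 3 + (di + 1);
          for (arma::uword j = 0; j < Wd; ++j) {
            const int jj = (int)j + dj;
            if (jj < 0 || jj >= (int)Wd) continue;
            for (arma::uword i = 0; i < H; ++i) {
              const int ii = (int)i + di;
              if (ii < 0 || ii >= (int)H) continue;
              dX(ii, jj, s * C + c) += dP(i + j * H, col);
            }
          }
        }
      }
    }
  }
  return List::create(Named("dX") = dX, Named("dW") = dW, Named("db") = db);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::cube& X) {
  const arma::uword H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const arma::uword H2 = H / 2, W2 = W / 2;
  arma::cube Y(H2, W2, C);
  arma::uvec idx(H2 * W2 * C);  // linear index into X, vectorise order of Y
  arma::uword t = 0;
  for (arma::uword c = 0; c < C; ++c) {
    for (arma::uword j = 0; j < W2; ++j) {
      for (arma::uword i = 0; i < H2; ++i) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (arma::uword dj = 0; dj < 2; ++dj) {
          for (arma::uword di = 0; di < 2; ++di) {
            const arma::uword ii = 2 * i + di, jj = 2 * j + dj;
            const double v = X(ii, jj, c);
            if (v > best) { best = v; bi = ii + jj * H + c * H * W; }
          }
        }
        Y(i, j, c) = best;
        idx(t++) = bi;
      }
    }
  }
  return List::create(Named("Y") = Y, Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::uvec& idx, const arma::cube& dY,
                            int H, int W) {
  const arma::uword C = dY.n_slices;
  arma::cube dX(H, W, C, arma::fill::zeros);
  arma::vec dyv = arma::vectorise(dY);
  double* px = dX.memptr();
  for (arma::uword t = 0; t < idx.n_elem; ++t) px[idx(t)] += dyv(t);
  return dX;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool_fwd(const arma::cube& X, int k) {
  const arma::uword H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const arma::uword H2 = H / k, W2 = W / k;
  arma::cube Y(H2, W2, C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword j = 0; j < W; ++j)
      for (arma::uword i = 0; i < H; ++i)
        Y(i / k, j / k, c) += X(i, j, c);
  Y /= (double)(k * k);
  return Y;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool_bwd(const arma::cube& dY, int k, int H, int W) {
  const arma::uword C = dY.n_slices;
  arma::cube dX(H, W, C);
  const double s = 1.0 / (double)(k * k);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword j = 0; j < (arma::uword)W; ++j)
      for (arma::uword i = 0; i < (arma::uword)H; ++i)
        dX(i, j, c) = dY(i / k, j / k, c) * s;
  return dX;
}
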