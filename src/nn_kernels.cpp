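// Low-level kernels for the fully convolutional regressors.
// Feature maps are (H, W, C) cubes (column-major, matching R arrays).
// Conv weights are (k*k*Cin) x Cout matrices with patch index
// ki + k*kj + k*k*ci (row offset fastest), "same" zero padding, odd k.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, r = k / 2;
  mat cols(k * k * C, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = ki + k * kj + k * k * c;
        const int di = ki - r, dj = kj - r;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i)
            cols(row, i + H * j) = xc(i + di, sj);
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, const int k) {
  const int H = x.n_rows, W = x.n_cols, Cout = w.n_cols;
  mat y;
  if (k == 1) {
    // 1x1 conv is a plain channel mix
    mat xm(const_cast<double*>(x.memptr()), H * W, x.n_slices, false, true);
    y = w.t() * xm.t();
  } else {
    y = w.t() * im2col(x, k);
  }
  y.each_col() += b;
  cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        out(i, j, c) = y(c, i + H * j);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& w,
                      const arma::cube& gy, const int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices, r = k / 2;
  mat Gy(Cout, H * W);
  for (int c = 0; c < Cout; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        Gy(c, i + H * j) = gy(i, j, c);
  vec gb = sum(Gy, 1);
  mat gw, gcols;
  cube gx(H, W, Cin, fill::zeros);
  if (k == 1) {
    mat xm(const_cast<double*>(x.memptr()), H * W, Cin, false, true);
    gw = (Gy * xm).t();
    mat gxm = (w * Gy).t(); // (HW x Cin)
    std::memcpy(gx.memptr(), gxm.memptr(), sizeof(double) * H * W * Cin);
  } else {
    mat cols = im2col(x, k);
    gw = cols * Gy.t();
    gcols = w * Gy; // (kkCin x HW)
    // col2im scatter-add
    for (int c = 0; c < Cin; ++c) {
      mat& gxc = gx.slice(c);
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const int row = ki + k * kj + k * k * c;
          const int di = ki - r, dj = kj - r;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dj;
            if (sj < 0 || sj >= W) continue;
            const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
            for (int i = i0; i < i1; ++i)
              gxc(i + di, sj) += gcols(row, i + H * j);
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// 2x2 max pooling, stride 2. idx holds 0-based linear indices into the
// input slice-wise plane extended by slice offset, i.e. into the full cube.
// [[Rcpp::export]]
Rcpp::List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int h = H / 2, w = W / 2;
  cube y(h, w, C);
  Rcpp::IntegerVector idx(h * w * C);
  int p = 0;
  for (int c = 0; c < C; ++c) {
    const long off = (long)c * H * W;
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        const int i0 = 2 * i, j0 = 2 * j;
        double best = x(i0, j0, c);
        int bi = i0, bj = j0;
        if (x(i0 + 1, j0, c) > best) { best = x(i0 + 1, j0, c); bi = i0 + 1; bj = j0; }
        if (x(i0, j0 + 1, c) > best) { best = x(i0, j0 + 1, c); bi = i0; bj = j0 + 1; }
        if (x(i0 + 1, j0 + 1, c) > best) { best = x(i0 + 1, j0 + 1, c); bi = i0 + 1; bj = j0 + 1; }
        y(i, j, c) = best;
        idx[p++] = (int)(off + bi + (long)H * bj);
      }
    }
  }
  idx.attr("dim") = Rcpp::IntegerVector::create(h, w, C);
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// Scatter values of v to positions idx in an (H, W, C) cube of zeros.
// Serves both as max-unpooling and as the pooling backward pass.
// [[Rcpp::export]]
arma::cube scatter_to(const arma::cube& v, const Rcpp::IntegerVector& idx,
                      const int H, const int W) {
  const int C = v.n_slices;
  cube out(H, W, C, fill::zeros);
  double* o = out.memptr();
  const double* vp = v.memptr();
  const int n = v.n_elem;
  for (int p = 0; p < n; ++p) o[idx[p]] += vp[p];
  return out;
}
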