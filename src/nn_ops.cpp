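// Compiled primitives for the small conv-net engine: 3x3 same-padding
// convolution (im2col + BLAS), 2x2 max pooling, 2x2 stride-2 transposed
// convolution and x2 bilinear upsampling, each with its backward pass.
// Feature maps are arma::cube (H x W x C, column-major per slice); conv
// weights are matrices with rows ordered (di fast, then dj, then channel):
// row = c*9 + (dj+1)*3 + (di+1).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col3(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(H * (size_t)W, 9 * (size_t)C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int col = c * 9 + (dj + 1) * 3 + (di + 1);
        double* o = out.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const double* src = x.slice_colptr(c, sj);
          const int i0 = (di < 0) ? 1 : 0;
          const int i1 = (di > 0) ? H - 1 : H;
          double* dst = o + (size_t)j * H;
          for (int i = i0; i < i1; ++i) dst[i] = src[i + di];
        }
      }
    }
  }
  return out;
}

static void col2im3_add(cube& gx, const mat& m) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int col = c * 9 + (dj + 1) * 3 + (di + 1);
        const double* o = m.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          double* dst = gx.slice_colptr(c, sj);
          const int i0 = (di < 0) ? 1 : 0;
          const int i1 = (di > 0) ? H - 1 : H;
          const double* src = o + (size_t)j * H;
          for (int i = i0; i < i1; ++i) dst[i + di] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv3_fw(const arma::cube& x, const arma::mat& w, const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  mat y = im2col3(x) * w;
  y.each_row() += b.t();
  return cube(y.memptr(), H, W, Cout);
}

// [[Rcpp::export]]
Rcpp::List conv3_bw(const arma::cube& x, const arma::mat& w, const arma::cube& gy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  mat gym(const_cast<double*>(gy.memptr()), (size_t)H * W, Cout, false, true);
  mat cols = im2col3(x);
  mat gw = cols.t() * gym;
  vec gb = sum(gym, 0).t();
  cube gx(H, W, Cin, fill::zeros);
  col2im3_add(gx, gym * w.t());
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
Rcpp::List maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  umat idx(Ho * (size_t)Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const int i = 2 * io, j = 2 * jo;
        double best = x(i, j, c);
        uword bi = (uword)c * H * W + (uword)j * H + i;
        const int ii[3] = {i + 1, i, i + 1};
        const int jj[3] = {j, j + 1, j + 1};
        for (int k = 0; k < 3; ++k) {
          const double v = x(ii[k], jj[k], c);
          if (v > best) {
            best = v;
            bi = (uword)c * H * W + (uword)jj[k] * H + ii[k];
          }
        }
        y(io, jo, c) = best;
        idx((size_t)jo * Ho + io, c) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bw(const arma::cube& gy, const arma::umat& idx,
                       int H, int W) {
  const int C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  const int n = gy.n_rows * gy.n_cols;
  for (int c = 0; c < C; ++c) {
    const double* g = gy.slice_colptr(c, 0);
    for (int k = 0; k < n; ++k) gx.memptr()[idx(k, c)] += g[k];
  }
  return gx;
}

// Transposed 2x2 stride-2 conv; w is (Cin x 4*Cout), column q*Cout+co with
// quadrant q = dj*2 + di, di/dj in {0,1}.
// [[Rcpp::export]]
arma::cube convt2_fw(const arma::cube& x, const arma::mat& w, const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_cols / 4;
  mat xm(const_cast<double*>(x.memptr()), (size_t)H * W, Cin, false, true);
  mat ym = xm * w;  // HW x 4Cout
  cube y(2 * H, 2 * W, Cout);
  for (int co = 0; co < Cout; ++co) {
    for (int dj = 0; dj < 2; ++dj) {
      for (int di = 0; di < 2; ++di) {
        const double* src = ym.colptr((size_t)(dj * 2 + di) * Cout + co);
        for (int j = 0; j < W; ++j) {
          double* dst = y.slice_colptr(co, 2 * j + dj) + di;
          const double* s = src + (size_t)j * H;
          for (int i = 0; i < H; ++i) dst[2 * i] = s[i] + b(co);
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List convt2_bw(const arma::cube& x, const arma::mat& w, const arma::cube& gy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  mat gym((size_t)H * W, 4 * (size_t)Cout);
  for (int co = 0; co < Cout; ++co) {
    for (int dj = 0; dj < 2; ++dj) {
      for (int di = 0; di < 2; ++di) {
        double* dst = gym.colptr((size_t)(dj * 2 + di) * Cout + co);
        for (int j = 0; j < W; ++j) {
          const double* src = gy.slice_colptr(co, 2 * j + dj) + di;
          double* d = dst + (size_t)j * H;
          for (int i = 0; i < H; ++i) d[i] = src[2 * i];
        }
      }
    }
  }
  mat xm(const_cast<double*>(x.memptr()), (size_t)H * W, Cin, false, true);
  mat gw = xm.t() * gym;
  mat gxm = gym * w.t();
  cube gx(gxm.memptr(), H, W, Cin);
  vec gb(Cout);
  for (int co = 0; co < Cout; ++co) {
    double s = 0;
    for (int q = 0; q < 4; ++q) s += accu(gym.col((size_t)q * Cout + co));
    gb(co) = s;
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// x2 bilinear upsampling (half-pixel centers): out o samples src o/2 - 0.25,
// clamped at borders. Separable; backward is the exact transpose.
static void up2_axis(int n, std::vector<int>& i0, std::vector<int>& i1,
                     std::vector<double>& w0) {
  i0.resize(2 * n); i1.resize(2 * n); w0.resize(2 * n);
  for (int o = 0; o < 2 * n; ++o) {
    const double s = 0.5 * o - 0.25;
    int lo = (int)std::floor(s);
    double w = 1.0 - (s - lo);
    int hi = lo + 1;
    if (lo < 0) { lo = 0; hi = 0; w = 1.0; }
    if (hi > n - 1) { hi = n - 1; lo = n - 1; w = 1.0; }
    i0[o] = lo; i1[o] = hi; w0[o] = w;
  }
}

// [[Rcpp::export]]
arma::cube up2_bilinear_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> rw, cw;
  up2_axis(H, r0, r1, rw);
  up2_axis(W, c0, c1, cw);
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i)
        y(i, j, c) = cw[j] * (rw[i] * x(r0[i], c0[j], c) + (1 - rw[i]) * x(r1[i], c0[j], c)) +
                     (1 - cw[j]) * (rw[i] * x(r0[i], c1[j], c) + (1 - rw[i]) * x(r1[i], c1[j], c));
  return y;
}

// [[Rcpp::export]]
arma::cube up2_bilinear_bw(const arma::cube& gy) {
  const int H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> rw, cw;
  up2_axis(H, r0, r1, rw);
  up2_axis(W, c0, c1, cw);
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i) {
        const double g = gy(i, j, c);
        gx(r0[i], c0[j], c) += cw[j] * rw[i] * g;
        gx(r1[i], c0[j], c) += cw[j] * (1 - rw[i]) * g;
        gx(r0[i], c1[j], c) += (1 - cw[j]) * rw[i] * g;
        gx(r1[i], c1[j], c) += (1 - cw[j]) * (1 - rw[i]) * g;
      }
  return gx;
}
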