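// Convolution / pooling / interpolation kernels for the 2D segmentation
// backbone. Layout: slices are arma::cube (H x W x C), weights for a k x k
// convolution are (k*k*Cin) x Cout with rows ordered channel-major, then
// column offset, then row offset (matching im2col below). "Same" padding,
// stride 1.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;
using Rcpp::List;

static mat im2col_same(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = k / 2;
  mat out(H * W, k * k * C);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    for (int dj = -p; dj <= p; ++dj) {
      for (int di = -p; di <= p; ++di) {
        double* dst = out.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) {
            for (int i = 0; i < H; ++i) dst[i + j * H] = 0.0;
            continue;
          }
          const double* src = x.slice_colptr(c, js);
          for (int i = 0; i < H; ++i) {
            const int is = i + di;
            dst[i + j * H] = (is < 0 || is >= H) ? 0.0 : src[is];
          }
        }
        ++col;
      }
    }
  }
  return out;
}

static cube col2im_same(const mat& cols, const int H, const int W,
                        const int C, const int k) {
  const int p = k / 2;
  cube x(H, W, C, fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    for (int dj = -p; dj <= p; ++dj) {
      for (int di = -p; di <= p; ++di) {
        const double* src = cols.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          double* dst = x.slice_colptr(c, js);
          for (int i = 0; i < H; ++i) {
            const int is = i + di;
            if (is >= 0 && is < H) dst[is] += src[i + j * H];
          }
        }
        ++col;
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, const int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  mat y = im2col_same(x, k) * w;
  y.each_row() += b.t();
  cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c) out.slice(c) = reshape(y.col(c), H, W);
  return out;
}

// [[Rcpp::export]]
List conv2d_bw(const arma::cube& x, const arma::mat& w, const arma::cube& gy,
               const int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  mat cols = im2col_same(x, k);
  mat gym(H * W, Cout);
  for (int c = 0; c < Cout; ++c) gym.col(c) = vectorise(gy.slice(c));
  mat gw = cols.t() * gym;
  vec gb = sum(gym, 0).t();
  cube gx = col2im_same(gym * w.t(), H, W, Cin, k);
  return List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                      Rcpp::Named("gb") = gb);
}

// 2x2 max pooling, stride 2, ceil semantics for odd sizes.
// idx stores the linear within-slice index (i + j*H) of the winner.
// [[Rcpp::export]]
List maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  cube y(Ho, Wo, C);
  cube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        double best = -datum::inf;
        int besti = -1;
        for (int dj = 0; dj < 2; ++dj) {
          const int j = 2 * jo + dj;
          if (j >= W) continue;
          for (int di = 0; di < 2; ++di) {
            const int i = 2 * io + di;
            if (i >= H) continue;
            const double v = x(i, j, c);
            if (v > best) { best = v; besti = i + j * H; }
          }
        }
        y(io, jo, c) = best;
        idx(io, jo, c) = besti;
      }
    }
  }
  return List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bw(const arma::cube& idx, const arma::cube& gy,
                       const int H, const int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* dst = gx.slice(c).memptr();
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io)
        dst[(int)idx(io, jo, c)] += gy(io, jo, c);
  }
  return gx;
}

static void bilin_coords(const int n_out, const int n_in, ivec& i0, ivec& i1,
                         vec& w1) {
  i0.set_size(n_out); i1.set_size(n_out); w1.set_size(n_out);
  for (int i = 0; i < n_out; ++i) {
    double src = (i + 0.5) * (double)n_in / n_out - 0.5;
    if (src < 0) src = 0;
    if (src > n_in - 1) src = n_in - 1;
    const int lo = (int)std::floor(src);
    i0[i] = lo;
    i1[i] = std::min(lo + 1, n_in - 1);
    w1[i] = src - lo;
  }
}

// bilinear resize to (H2, W2). With H2 == H and W2 == W this is an exact
// identity (the source coordinate reduces to the integer index).
// [[Rcpp::export]]
arma::cube bilin_fw(const arma::cube& x, const int H2, const int W2) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  ivec ri0, ri1, cj0, cj1;
  vec rw, cw;
  bilin_coords(H2, H, ri0, ri1, rw);
  bilin_coords(W2, W, cj0, cj1, cw);
  cube y(H2, W2, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W2; ++j) {
      const double wj = cw[j];
      for (int i = 0; i < H2; ++i) {
        const double wi = rw[i];
        y(i, j, c) =
          (1 - wi) * (1 - wj) * x(ri0[i], cj0[j], c) +
          wi * (1 - wj) * x(ri1[i], cj0[j], c) +
          (1 - wi) * wj * x(ri0[i], cj1[j], c) +
          wi * wj * x(ri1[i], cj1[j], c);
      }
    }
  }
  return y;
}

// adjoint of bilin_fw: scatter output gradients back to an (H, W) grid
// [[Rcpp::export]]
arma::cube bilin_bw(const arma::cube& gy, const int H, const int W) {
  const int H2 = gy.n_rows, W2 = gy.n_cols, C = gy.n_slices;
  ivec ri0, ri1, cj0, cj1;
  vec rw, cw;
  bilin_coords(H2, H, ri0, ri1, rw);
  bilin_coords(W2, W, cj0, cj1, cw);
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W2; ++j) {
      const double wj = cw[j];
      for (int i = 0; i < H2; ++i) {
        const double wi = rw[i];
        const double g = gy(i, j, c);
        gx(ri0[i], cj0[j], c) += (1 - wi) * (1 - wj) * g;
        gx(ri1[i], cj0[j], c) += wi * (1 - wj) * g;
        gx(ri0[i], cj1[j], c) += (1 - wi) * wj * g;
        gx(ri1[i], cj1[j], c) += wi * wj * g;
      }
    }
  }
  return gx;
}

// boundary-to-boundary nearest distances: for each row of `a` (points, mm),
// the distance to the nearest row of `b`
// [[Rcpp::export]]
arma::vec nearest_distances(const arma::mat& a, const arma::mat& b) {
  const int na = a.n_rows, nb = b.n_rows;
  vec out(na);
  for (int i = 0; i < na; ++i) {
    double best = datum::inf;
    const double x = a(i, 0), y = a(i, 1), z = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      const double dx = x - b(j, 0), dy = y - b(j, 1), dz = z - b(j, 2);
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---- small dense-net helpers (hot paths of the MLP stages) -----------------

// exact-size random subset masks: row v keeps nv[v] of m entries, chosen by
// the nv smallest of the supplied uniforms (column-major B x M matrix)
// [[Rcpp::export]]
Rcpp::LogicalMatrix subset_masks(const arma::mat& u, const arma::ivec& nv) {
  const int B = u.n_rows, M = u.n_cols;
  Rcpp::LogicalMatrix out(B, M);
  std::vector<double> row(M);
  for (int i = 0; i < B; ++i) {
    for (int j = 0; j < M; ++j) row[j] = u(i, j);
    std::vector<double> tmp(row);
    const int k = nv[i];
    std::nth_element(tmp.begin(), tmp.begin() + (k - 1), tmp.end());
    const double thr = tmp[k - 1];
    int taken = 0;
    for (int j = 0; j < M; ++j) {
      if (row[j] <= thr && taken < k) { out(i, j) = TRUE; ++taken; }
    }
  }
  return out;
}

// fused dense layer forward: relu(A W + b) or A W + b
// [[Rcpp::export]]
arma::mat dense_fw(const arma::mat& A, const arma::mat& W, const arma::vec& b,
                   const bool relu) {
  mat Z = A * W;
  Z.each_row() += b.t();
  if (relu) Z = clamp(Z, 0.0, datum::inf);
  return Z;
}

// fused dense layer input-gradient: (G W') masked by the ReLU of the
// previous post-activation
// [[Rcpp::export]]
arma::mat dense_bw_input(const arma::mat& G, const arma::mat& W,
                         const arma::mat& a_post, const bool mask) {
  mat gx = G * W.t();
  if (mask) gx.elem(find(a_post <= 0)).zeros();
  return gx;
}
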