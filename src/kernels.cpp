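// Numerical kernels for the segmentation network.
//
// Feature maps are passed as (N*H*W) x C matrices in row-major pixel order
// within each sample: row index = n*H*W + y*W + x (0-based), i.e. y is the
// image row (top to bottom) and x the column (left to right). Kernels are
// (k*k*Cin) x Cout matrices whose row index is ky + kx*k + c*k*k, matching
// the column-major flattening of an R array with dim c(k, k, Cin, Cout).

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void im2col_sample(const arma::mat& X, int n, int H, int W, int C,
                                 int k, int stride, int pad, arma::mat& cols,
                                 int Ho, int Wo) {
  const int base = n * H * W;
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int col = ky + kx * k + c * k * k;
        for (int oy = 0; oy < Ho; ++oy) {
          const int iy = oy * stride - pad + ky;
          for (int ox = 0; ox < Wo; ++ox) {
            const int ix = ox * stride - pad + kx;
            double v = 0.0;
            if (iy >= 0 && iy < H && ix >= 0 && ix < W)
              v = X(base + iy * W + ix, c);
            cols(oy * Wo + ox, col) = v;
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
arma::mat conv2d_fwd(const arma::mat& X, int N, int H, int W, int C,
                     const arma::mat& K, int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int Co = K.n_cols;
  arma::mat Y(N * Ho * Wo, Co);
  arma::mat cols(Ho * Wo, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col_sample(X, n, H, W, C, k, stride, pad, cols, Ho, Wo);
    Y.rows(n * Ho * Wo, (n + 1) * Ho * Wo - 1) = cols * K;
  }
  return Y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(const arma::mat& X, const arma::mat& dY, int N, int H, int W,
                int C, const arma::mat& K, int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat dX(N * H * W, C, arma::fill::zeros);
  arma::mat dK(K.n_rows, K.n_cols, arma::fill::zeros);
  arma::mat cols(Ho * Wo, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col_sample(X, n, H, W, C, k, stride, pad, cols, Ho, Wo);
    const arma::mat dYs = dY.rows(n * Ho * Wo, (n + 1) * Ho * Wo - 1);
    dK += cols.t() * dYs;
    const arma::mat dcols = dYs * K.t();  // (Ho*Wo) x (k*k*C)
    const int base = n * H * W;
    for (int c = 0; c < C; ++c) {
      for (int kx = 0; kx < k; ++kx) {
        for (int ky = 0; ky < k; ++ky) {
          const int col = ky + kx * k + c * k * k;
          for (int oy = 0; oy < Ho; ++oy) {
            const int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= H) continue;
            for (int ox = 0; ox < Wo; ++ox) {
              const int ix = ox * stride - pad + kx;
              if (ix < 0 || ix >= W) continue;
              dX(base + iy * W + ix, c) += dcols(oy * Wo + ox, col);
            }
          }
        }
      }
    }
  }
  return List::create(Named("dx") = dX, Named("dk") = dK);
}

// Depthwise convolution: K is (k*k) x C, one k x k filter per channel.
// [[Rcpp::export(name = ".dwconv_fwd")]]
arma::mat dwconv_fwd(const arma::mat& X, int N, int H, int W, int C,
                     const arma::mat& K, int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat Y(N * Ho * Wo, C, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const int base = n * H * W, obase = n * Ho * Wo;
    for (int c = 0; c < C; ++c) {
      for (int kx = 0; kx < k; ++kx) {
        for (int ky = 0; ky < k; ++ky) {
          const double w = K(ky + kx * k, c);
          if (w == 0.0) continue;
          for (int oy = 0; oy < Ho; ++oy) {
            const int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= H) continue;
            for (int ox = 0; ox < Wo; ++ox) {
              const int ix = ox * stride - pad + kx;
              if (ix < 0 || ix >= W) continue;
              Y(obase + oy * Wo + ox, c) += w * X(base + iy * W + ix, c);
            }
          }
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".dwconv_bwd")]]
List dwconv_bwd(const arma::mat& X, const arma::mat& dY, int N, int H, int W,
                int C, const arma::mat& K, int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat dX(N * H * W, C, arma::fill::zeros);
  arma::mat dK(k * k, C, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const int base = n * H * W, obase = n * Ho * Wo;
    for (int c = 0; c < C; ++c) {
      for (int kx = 0; kx < k; ++kx) {
        for (int ky = 0; ky < k; ++ky) {
          const double w = K(ky + kx * k, c);
          double acc = 0.0;
          for (int oy = 0; oy < Ho; ++oy) {
            const int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= H) continue;
            for (int ox = 0; ox < Wo; ++ox) {
              const int ix = ox * stride - pad + kx;
              if (ix < 0 || ix >= W) continue;
              const double g = dY(obase + oy * Wo + ox, c);
              acc += g * X(base + iy * W + ix, c);
              dX(base + iy * W + ix, c) += g * w;
            }
          }
          dK(ky + kx * k, c) += acc;
        }
      }
    }
  }
  return List::create(Named("dx") = dX, Named("dk") = dK);
}

// Per-channel diagonal linear state-space scan.
//   h_t = a (.) h_{t-1} + b * x_t      (h in R^S per channel, h_0 = 0)
//   y_t = <c, h_t> + d * x_t
// X, Y are (N*T) x C; A, B, Cm are C x S; D is length C.
// [[Rcpp::export(name = ".ssm_scan_fwd")]]
arma::mat ssm_scan_fwd(const arma::mat& X, int N, int T, int C,
                       const arma::mat& A, const arma::mat& B,
                       const arma::mat& Cm, const arma::vec& D) {
  const int S = A.n_cols;
  arma::mat Y(N * T, C);
  std::vector<double> a(S), b(S), cc(S), h(S);
  for (int c = 0; c < C; ++c) {
    for (int s = 0; s < S; ++s) { a[s] = A(c, s); b[s] = B(c, s); cc[s] = Cm(c, s); }
    const double d = D(c);
    const double* xp = X.colptr(c);
    double* yp = Y.colptr(c);
    for (int n = 0; n < N; ++n) {
      const int base = n * T;
      std::fill(h.begin(), h.end(), 0.0);
      for (int t = 0; t < T; ++t) {
        const double x = xp[base + t];
        double y = d * x;
        for (int s = 0; s < S; ++s) {
          h[s] = a[s] * h[s] + b[s] * x;
          y += cc[s] * h[s];
        }
        yp[base + t] = y;
      }
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".ssm_scan_bwd")]]
List ssm_scan_bwd(const arma::mat& X, const arma::mat& dY, int N, int T, int C,
                  const arma::mat& A, const arma::mat& B, const arma::mat& Cm,
                  const arma::vec& D) {
  const int S = A.n_cols;
  arma::mat dX(N * T, C), dA(C, S, arma::fill::zeros),
      dB(C, S, arma::fill::zeros), dC(C, S, arma::fill::zeros);
  arma::vec dD(C, arma::fill::zeros);
  std::vector<double> a(S), b(S), cc(S), h(S), dh(S),
      das(S), dbs(S), dcs(S), hstore((size_t)S * T);
  for (int c = 0; c < C; ++c) {
    for (int s = 0; s < S; ++s) {
      a[s] = A(c, s); b[s] = B(c, s); cc[s] = Cm(c, s);
      das[s] = dbs[s] = dcs[s] = 0.0;
    }
    const double d = D(c);
    double dd = 0.0;
    const double* xp = X.colptr(c);
    const double* gp = dY.colptr(c);
    double* dxp = dX.colptr(c);
    for (int n = 0; n < N; ++n) {
      const int base = n * T;
      // forward recomputation of the hidden trajectory
      std::fill(h.begin(), h.end(), 0.0);
      for (int t = 0; t < T; ++t) {
        const double x = xp[base + t];
        double* hs = &hstore[(size_t)S * t];
        for (int s = 0; s < S; ++s) {
          h[s] = a[s] * h[s] + b[s] * x;
          hs[s] = h[s];
        }
      }
      std::fill(dh.begin(), dh.end(), 0.0);
      for (int t = T - 1; t >= 0; --t) {
        const double x = xp[base + t];
        const double g = gp[base + t];
        dd += g * x;
        double dx = d * g;
        const double* hs = &hstore[(size_t)S * t];
        const double* hp = (t > 0) ? &hstore[(size_t)S * (t - 1)] : nullptr;
        for (int s = 0; s < S; ++s) {
          dcs[s] += g * hs[s];
          const double dhs = cc[s] * g + dh[s];
          if (hp) das[s] += dhs * hp[s];
          dbs[s] += dhs * x;
          dx += b[s] * dhs;
          dh[s] = a[s] * dhs;  // carried to t-1
        }
        dxp[base + t] = dx;
      }
    }
    dD(c) = dd;
    for (int s = 0; s < S; ++s) { dA(c, s) = das[s]; dB(c, s) = dbs[s]; dC(c, s) = dcs[s]; }
  }
  return List::create(Named("dx") = dX, Named("da") = dA, Named("db") = dB,
                      Named("dc") = dC, Named("dd") = dD);
}
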