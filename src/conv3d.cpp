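// Dense 3D convolution kernels (slab-wise im2col + BLAS) used by the
// generator and critic networks. Volumes are R arrays with dim (D1, D2, D3,
// C); kernels are arrays with dim (k, k, k, Cin, Cout). Zero padding;
// floor-division output size Do = (D + 2p - k) / s + 1, so the adjoint
// (fractional-stride) pass naturally carries output_padding = 1 when s = 2,
// k = 3, p = 1. The im2col buffer is built for a slab of output z-planes at
// a time to bound memory at large volume sizes.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double MAX_BUF_ELEMS = 8.0e6;  // ~64 MB im2col buffer cap

static void im2col_slab(const double* x, const int* xd, int k, int stride,
                        int pad, int o3s, int o3n, const int* od, arma::mat& Kt) {
  const int D1 = xd[0], D2 = xd[1], D3 = xd[2], C = xd[3];
  const int O1 = od[0], O2 = od[1];
  const arma::uword nRows = (arma::uword)O1 * O2 * o3n;
  Kt.zeros(nRows, (arma::uword)k * k * k * C);
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)ci * D1 * D2 * D3;
    for (int l = 0; l < k; ++l) {
      for (int j = 0; j < k; ++j) {
        for (int i = 0; i < k; ++i) {
          const arma::uword col = i + (arma::uword)k * (j + (arma::uword)k * (l + (arma::uword)k * ci));
          double* Kcol = Kt.colptr(col);
          for (int t = 0; t < o3n; ++t) {
            const int in3 = (o3s + t) * stride + l - pad;
            if (in3 < 0 || in3 >= D3) continue;
            for (int o2 = 0; o2 < O2; ++o2) {
              const int in2 = o2 * stride + j - pad;
              if (in2 < 0 || in2 >= D2) continue;
              for (int o1 = 0; o1 < O1; ++o1) {
                const int in1 = o1 * stride + i - pad;
                if (in1 < 0 || in1 >= D1) continue;
                Kcol[o1 + (size_t)O1 * (o2 + (size_t)O2 * t)] =
                    xc[in1 + (size_t)D1 * (in2 + (size_t)D2 * in3)];
              }
            }
          }
        }
      }
    }
  }
}

static void out_dims(const int* xd, int k, int stride, int pad, int* od) {
  for (int a = 0; a < 3; ++a) od[a] = (xd[a] + 2 * pad - k) / stride + 1;
}

static int slab_planes(const int* od, int k, int Cin) {
  double rowCost = (double)od[0] * od[1] * k * k * k * Cin;
  int planes = (int)std::max(1.0, MAX_BUF_ELEMS / std::max(rowCost, 1.0));
  return std::min(planes, od[2]);
}

// [[Rcpp::export]]
NumericVector cg_conv3d_fwd(NumericVector x, IntegerVector xdim,
                            NumericVector w, IntegerVector wdim,
                            int stride, int pad) {
  const int k = wdim[0], Cin = wdim[3], Cout = wdim[4];
  if (xdim[3] != Cin) stop("channel mismatch: input has %d, kernel expects %d", (int)xdim[3], Cin);
  int od[3];
  out_dims(INTEGER(xdim), k, stride, pad, od);
  if (od[0] < 1 || od[1] < 1 || od[2] < 1) stop("convolution output would be empty");
  const arma::uword nOut = (arma::uword)od[0] * od[1] * od[2];
  const arma::mat Wm(w.begin(), (arma::uword)k * k * k * Cin, Cout, false, true);
  NumericVector out((R_xlen_t)nOut * Cout);
  out.attr("dim") = IntegerVector::create(od[0], od[1], od[2], Cout);
  const int slab = slab_planes(od, k, Cin);
  arma::mat Kt;
  for (int o3s = 0; o3s < od[2]; o3s += slab) {
    const int o3n = std::min(slab, od[2] - o3s);
    im2col_slab(x.begin(), INTEGER(xdim), k, stride, pad, o3s, o3n, od, Kt);
    arma::mat Y = Kt * Wm;  // (slabRows x Cout)
    const size_t rowOff = (size_t)od[0] * od[1] * o3s;
    for (int c = 0; c < Cout; ++c) {
      std::copy(Y.colptr(c), Y.colptr(c) + Y.n_rows,
                out.begin() + (size_t)c * nOut + rowOff);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cg_conv3d_bwd_w(NumericVector x, IntegerVector xdim,
                              NumericVector gy, IntegerVector ydim,
                              int k, int stride, int pad) {
  const int Cin = xdim[3], Cout = ydim[3];
  int od[3] = {ydim[0], ydim[1], ydim[2]};
  const arma::uword nOut = (arma::uword)od[0] * od[1] * od[2];
  arma::mat Gw((arma::uword)k * k * k * Cin, Cout, arma::fill::zeros);
  const int slab = slab_planes(od, k, Cin);
  arma::mat Kt, Gs;
  for (int o3s = 0; o3s < od[2]; o3s += slab) {
    const int o3n = std::min(slab, od[2] - o3s);
    im2col_slab(x.begin(), INTEGER(xdim), k, stride, pad, o3s, o3n, od, Kt);
    const size_t rowOff = (size_t)od[0] * od[1] * o3s;
    Gs.set_size(Kt.n_rows, Cout);
    for (int c = 0; c < Cout; ++c) {
      std::copy(gy.begin() + (size_t)c * nOut + rowOff,
                gy.begin() + (size_t)c * nOut + rowOff + Kt.n_rows, Gs.colptr(c));
    }
    Gw += Kt.t() * Gs;
  }
  NumericVector out(Gw.begin(), Gw.end());
  out.attr("dim") = IntegerVector::create(k, k, k, Cin, Cout);
  return out;
}

// [[Rcpp::export]]
NumericVector cg_conv3d_bwd_x(NumericVector gy, IntegerVector ydim,
                              NumericVector w, IntegerVector wdim,
                              int stride, int pad, IntegerVector xdim) {
  const int k = wdim[0], Cin = wdim[3], Cout = wdim[4];
  const int D1 = xdim[0], D2 = xdim[1], D3 = xdim[2];
  int od[3] = {ydim[0], ydim[1], ydim[2]};
  const arma::uword nOut = (arma::uword)od[0] * od[1] * od[2];
  const arma::mat Wm(w.begin(), (arma::uword)k * k * k * Cin, Cout, false, true);
  NumericVector gx((R_xlen_t)D1 * D2 * D3 * Cin);
  gx.attr("dim") = IntegerVector::create(D1, D2, D3, Cin);
  double* gxp = gx.begin();
  const int slab = slab_planes(od, k, Cin);
  arma::mat Gs, dKt;
  for (int o3s = 0; o3s < od[2]; o3s += slab) {
    const int o3n = std::min(slab, od[2] - o3s);
    const arma::uword nRows = (arma::uword)od[0] * od[1] * o3n;
    const size_t rowOff = (size_t)od[0] * od[1] * o3s;
    Gs.set_size(nRows, Cout);
    for (int c = 0; c < Cout; ++c) {
      std::copy(gy.begin() + (size_t)c * nOut + rowOff,
                gy.begin() + (size_t)c * nOut + rowOff + nRows, Gs.colptr(c));
    }
    dKt = Gs * Wm.t();  // (slabRows x k^3*Cin)
    for (int ci = 0; ci < Cin; ++ci) {
      double* gxc = gxp + (size_t)ci * D1 * D2 * D3;
      for (int l = 0; l < k; ++l) {
        for (int j = 0; j < k; ++j) {
          for (int i = 0; i < k; ++i) {
            const arma::uword col = i + (arma::uword)k * (j + (arma::uword)k * (l + (arma::uword)k * ci));
            const double* Dcol = dKt.colptr(col);
            for (int t = 0; t < o3n; ++t) {
              const int in3 = (o3s + t) * stride + l - pad;
              if (in3 < 0 || in3 >= D3) continue;
              for (int o2 = 0; o2 < od[1]; ++o2) {
                const int in2 = o2 * stride + j - pad;
                if (in2 < 0 || in2 >= D2) continue;
                for (int o1 = 0; o1 < od[0]; ++o1) {
                  const int in1 = o1 * stride + i - pad;
                  if (in1 < 0 || in1 >= D1) continue;
                  gxc[in1 + (size_t)D1 * (in2 + (size_t)D2 * in3)] +=
                      Dcol[o1 + (size_t)od[0] * (o2 + (size_t)od[1] * t)];
                }
              }
            }
          }
        }
      }
    }
  }
  return gx;
}
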