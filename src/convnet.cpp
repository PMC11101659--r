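// Compute kernels for the convolutional feature extractors: im2col-based
// 3x3 same-padding convolution (forward and adjoint) and 2x2 ceiling
// max-pooling. Column ordering of the im2col matrix is channel-major, then
// patch column, then patch row (row index fastest), matching the R-side
// weight layout (k*k*cin) x cout.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <dlfcn.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// The conv matmuls are small; multi-threaded BLAS only adds synchronisation
// overhead there. Resolved at runtime so any BLAS lacking the OpenBLAS
// entry points degrades to a no-op.

// [[Rcpp::export]]
int blas_threads_cpp(int n) {
  typedef void (*set_fn)(int);
  typedef int (*get_fn)(void);
  get_fn get = (get_fn) dlsym(RTLD_DEFAULT, "openblas_get_num_threads");
  set_fn set = (set_fn) dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
  int old = get ? get() : -1;
  if (set && n > 0) set(n);
  return old;
}

// Bilinear inverse warp: output pixel (r, c) samples the input at
// (a11*r + a12*c + t1, a21*r + a22*c + t2), 0-based coordinates. border = 0
// fills outside with zero, border = 1 clamps to the edge.
// [[Rcpp::export]]
arma::cube warp_bilinear_cpp(const arma::cube& x, int ho, int wo,
                             double a11, double a12, double a21, double a22,
                             double t1, double t2, int border) {
  const int h = x.n_rows, w = x.n_cols, nc = x.n_slices;
  arma::cube out(ho, wo, nc, arma::fill::zeros);
  for (int c = 0; c < wo; ++c)
    for (int r = 0; r < ho; ++r) {
      double sr = a11 * r + a12 * c + t1;
      double sc = a21 * r + a22 * c + t2;
      if (border == 1) {
        sr = std::min(std::max(sr, 0.0), (double)(h - 1));
        sc = std::min(std::max(sc, 0.0), (double)(w - 1));
      } else if (sr < -1 || sr > h || sc < -1 || sc > w) {
        continue;
      }
      const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      const double fr = sr - r0, fc = sc - c0;
      for (int ch = 0; ch < nc; ++ch) {
        double acc = 0.0;
        for (int dc = 0; dc < 2; ++dc)
          for (int dr = 0; dr < 2; ++dr) {
            const int rr = r0 + dr, cc2 = c0 + dc;
            if (rr < 0 || rr >= h || cc2 < 0 || cc2 >= w) continue;
            acc += x(rr, cc2, ch) * (dr ? fr : 1 - fr) * (dc ? fc : 1 - fc);
          }
        out(r, c, ch) = acc;
      }
    }
  return out;
}

static arma::mat build_im2col(const arma::cube& x) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices, k = 3, p = 1;
  arma::mat xcol(h * w, k * k * cin, arma::fill::zeros);
  for (int ch = 0; ch < cin; ++ch)
    for (int dc = 0; dc < k; ++dc)
      for (int dr = 0; dr < k; ++dr) {
        const int j = (ch * k + dc) * k + dr;
        for (int c = 0; c < w; ++c) {
          const int ic = c + dc - p;
          if (ic < 0 || ic >= w) continue;
          for (int r = 0; r < h; ++r) {
            const int ir = r + dr - p;
            if (ir < 0 || ir >= h) continue;
            xcol(r + c * h, j) = x(ir, ic, ch);
          }
        }
      }
  return xcol;
}

// [[Rcpp::export]]
List conv3_forward_cpp(const arma::cube& x, const arma::mat& W,
                       const arma::vec& b) {
  const int h = x.n_rows, w = x.n_cols;
  arma::mat xcol = build_im2col(x);
  arma::mat y = xcol * W;
  y.each_row() += b.t();
  arma::cube yc(y.memptr(), h, w, W.n_cols);
  return List::create(_["y"] = yc, _["xcol"] = xcol);
}

// [[Rcpp::export]]
List conv3_backward_cpp(const arma::mat& gy, const arma::mat& xcol,
                        const arma::mat& W, int h, int w, int cin) {
  const int k = 3, p = 1;
  arma::mat gW = xcol.t() * gy;
  arma::vec gb = arma::sum(gy, 0).t();
  arma::mat gcol = gy * W.t();
  arma::cube gx(h, w, cin, arma::fill::zeros);
  for (int ch = 0; ch < cin; ++ch)
    for (int dc = 0; dc < k; ++dc)
      for (int dr = 0; dr < k; ++dr) {
        const int j = (ch * k + dc) * k + dr;
        for (int c = 0; c < w; ++c) {
          const int ic = c + dc - p;
          if (ic < 0 || ic >= w) continue;
          for (int r = 0; r < h; ++r) {
            const int ir = r + dr - p;
            if (ir < 0 || ir >= h) continue;
            gx(ir, ic, ch) += gcol(r + c * h, j);
          }
        }
      }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool2_forward_cpp(const arma::cube& x) {
  const int h = x.n_rows, w = x.n_cols, nc = x.n_slices;
  const int ho = (h + 1) / 2, wo = (w + 1) / 2;
  arma::cube y(ho, wo, nc);
  IntegerVector argmax(ho * wo * nc);
  for (int ch = 0; ch < nc; ++ch)
    for (int c = 0; c < wo; ++c)
      for (int r = 0; r < ho; ++r) {
        double best = -1e300;
        int bi = -1;
        for (int dc = 0; dc < 2; ++dc) {
          const int ic = 2 * c + dc;
          if (ic >= w) continue;
          for (int dr = 0; dr < 2; ++dr) {
            const int ir = 2 * r + dr;
            if (ir >= h) continue;
            const double v = x(ir, ic, ch);
            if (v > best) { best = v; bi = ir + ic * h + ch * h * w; }
          }
        }
        y(r, c, ch) = best;
        argmax[r + c * ho + ch * ho * wo] = bi + 1;  // 1-based for R
      }
  return List::create(_["y"] = y, _["argmax"] = argmax);
}

// [[Rcpp::export]]
arma::cube maxpool2_backward_cpp(const arma::vec& gy,
                                 const IntegerVector& argmax,
                                 int h, int w, int nc) {
  arma::cube gx(h, w, nc, arma::fill::zeros);
  for (int i = 0; i < argmax.size(); ++i)
    gx(argmax[i] - 1) = gy[i];   // pooling windows are disjoint
  return gx;
}
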