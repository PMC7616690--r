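// Low-level tensor kernels for the 3D CNN and the differentiable warp.
//
// Tensor layout: feature maps are numeric arrays with dim = c(C, H, W, D)
// (channel-fastest, column-major), single-channel volumes are (H, W, D).
// Convolution weights are matrices of shape (Cout x Cin_per_group*kh*kw*kd)
// with the column index ordered channel-fastest, then kh, kw, kd — matching
// the im2col row order used here.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// Fill the im2col matrix for one output-depth slab.
// col: (Cing*kh*kw*kd) x (Ho*Wo), for group g and output depth do_.
static void im2col_slab(const double* x, int Cin, int H, int W, int D,
                        int g, int Cing,
                        int kh, int kw, int kd, int sh, int sw, int sd,
                        int ph, int pw, int pd,
                        int Ho, int Wo, int do_, arma::mat& col) {
  col.zeros();
  const int c0 = g * Cing;
  for (int kdi = 0; kdi < kd; ++kdi) {
    const int din = do_ * sd - pd + kdi;
    if (din < 0 || din >= D) continue;
    for (int kwi = 0; kwi < kw; ++kwi) {
      for (int khi = 0; khi < kh; ++khi) {
        const int row0 = Cing * (khi + kh * (kwi + kw * kdi));
        for (int wo = 0; wo < Wo; ++wo) {
          const int win = wo * sw - pw + kwi;
          if (win < 0 || win >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hin = ho * sh - ph + khi;
            if (hin < 0 || hin >= H) continue;
            const double* src = x + (size_t)c0 +
              (size_t)Cin * ((size_t)hin + (size_t)H * ((size_t)win + (size_t)W * din));
            double* dst = col.colptr(ho + Ho * wo) + row0;
            for (int c = 0; c < Cing; ++c) dst[c] = src[c];
          }
        }
      }
    }
  }
}

// Scatter-add the adjoint of im2col for one slab back into gx.
static void col2im_slab(double* gx, int Cin, int H, int W, int D,
                        int g, int Cing,
                        int kh, int kw, int kd, int sh, int sw, int sd,
                        int ph, int pw, int pd,
                        int Ho, int Wo, int do_, const arma::mat& col) {
  const int c0 = g * Cing;
  for (int kdi = 0; kdi < kd; ++kdi) {
    const int din = do_ * sd - pd + kdi;
    if (din < 0 || din >= D) continue;
    for (int kwi = 0; kwi < kw; ++kwi) {
      for (int khi = 0; khi < kh; ++khi) {
        const int row0 = Cing * (khi + kh * (kwi + kw * kdi));
        for (int wo = 0; wo < Wo; ++wo) {
          const int win = wo * sw - pw + kwi;
          if (win < 0 || win >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hin = ho * sh - ph + khi;
            if (hin < 0 || hin >= H) continue;
            double* dst = gx + (size_t)c0 +
              (size_t)Cin * ((size_t)hin + (size_t)H * ((size_t)win + (size_t)W * din));
            const double* src = col.colptr(ho + Ho * wo) + row0;
            for (int c = 0; c < Cing; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fw_cpp(NumericVector x, IntegerVector dimx,
                            NumericMatrix w, Nullable<NumericVector> bias,
                            IntegerVector kern, IntegerVector stride,
                            IntegerVector pad, int groups) {
  const int Cin = dimx[0], H = dimx[1], W = dimx[2], D = dimx[3];
  const int kh = kern[0], kw = kern[1], kd = kern[2];
  const int sh = stride[0], sw = stride[1], sd = stride[2];
  const int ph = pad[0], pw = pad[1], pd = pad[2];
  const int Cout = w.nrow();
  const int Cing = Cin / groups, Coutg = Cout / groups;
  const int K = Cing * kh * kw * kd;
  if (w.ncol() != K) stop("weight matrix has %d cols, expected %d", w.ncol(), K);
  const int Ho = out_size(H, kh, sh, ph), Wo = out_size(W, kw, sw, pw),
            Do = out_size(D, kd, sd, pd);
  NumericVector y((size_t)Cout * Ho * Wo * Do);
  y.attr("dim") = IntegerVector::create(Cout, Ho, Wo, Do);
  arma::mat wm(w.begin(), Cout, K, false, true);
  arma::mat col(K, (size_t)Ho * Wo);
  arma::vec b;
  bool has_b = bias.isNotNull();
  if (has_b) b = as<arma::vec>(bias.get());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int do_ = 0; do_ < Do; ++do_) {
    for (int g = 0; g < groups; ++g) {
      im2col_slab(xp, Cin, H, W, D, g, Cing, kh, kw, kd, sh, sw, sd,
                  ph, pw, pd, Ho, Wo, do_, col);
      arma::mat wg = wm.rows(g * Coutg, (g + 1) * Coutg - 1);
      arma::mat ys = wg * col;  // Coutg x (Ho*Wo)
      if (has_b) ys.each_col() += b.subvec(g * Coutg, (g + 1) * Coutg - 1);
      // write into y(c, ho, wo, do_)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double* dst = yp + (size_t)g * Coutg +
            (size_t)Cout * ((size_t)ho + (size_t)Ho * ((size_t)wo + (size_t)Wo * do_));
          const double* src = ys.colptr(ho + Ho * wo);
          for (int c = 0; c < Coutg; ++c) dst[c] = src[c];
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_bw_cpp(NumericVector x, IntegerVector dimx,
                   NumericMatrix w, NumericVector gy,
                   IntegerVector kern, IntegerVector stride,
                   IntegerVector pad, int groups, bool has_bias) {
  const int Cin = dimx[0], H = dimx[1], W = dimx[2], D = dimx[3];
  const int kh = kern[0], kw = kern[1], kd = kern[2];
  const int sh = stride[0], sw = stride[1], sd = stride[2];
  const int ph = pad[0], pw = pad[1], pd = pad[2];
  const int Cout = w.nrow();
  const int Cing = Cin / groups, Coutg = Cout / groups;
  const int K = Cing * kh * kw * kd;
  const int Ho = out_size(H, kh, sh, ph), Wo = out_size(W, kw, sw, pw),
            Do = out_size(D, kd, sd, pd);
  NumericVector gx((size_t)Cin * H * W * D);
  gx.attr("dim") = dimx;
  NumericMatrix gw(Cout, K);
  NumericVector gb(has_bias ? Cout : 0);
  arma::mat wm(w.begin(), Cout, K, false, true);
  arma::mat gwm(gw.begin(), Cout, K, false, true);
  arma::mat col(K, (size_t)Ho * Wo);
  arma::mat gys(Coutg, (size_t)Ho * Wo);
  const double* xp = x.begin();
  const double* gyp = gy.begin();
  double* gxp = gx.begin();
  for (int do_ = 0; do_ < Do; ++do_) {
    for (int g = 0; g < groups; ++g) {
      // gather gy slab for this group
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double* src = gyp + (size_t)g * Coutg +
            (size_t)Cout * ((size_t)ho + (size_t)Ho * ((size_t)wo + (size_t)Wo * do_));
          double* dst = gys.colptr(ho + Ho * wo);
          for (int c = 0; c < Coutg; ++c) dst[c] = src[c];
        }
      im2col_slab(xp, Cin, H, W, D, g, Cing, kh, kw, kd, sh, sw, sd,
                  ph, pw, pd, Ho, Wo, do_, col);
      gwm.rows(g * Coutg, (g + 1) * Coutg - 1) += gys * col.t();
      arma::mat wg = wm.rows(g * Coutg, (g + 1) * Coutg - 1);
      arma::mat gcol = wg.t() * gys;
      col2im_slab(gxp, Cin, H, W, D, g, Cing, kh, kw, kd, sh, sw, sd,
                  ph, pw, pd, Ho, Wo, do_, gcol);
      if (has_bias) {
        arma::vec s = arma::sum(gys, 1);
        for (int c = 0; c < Coutg; ++c) gb[g * Coutg + c] += s[c];
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Half-pixel (align_corners = FALSE) trilinear resize, channels-first.
// [[Rcpp::export]]
NumericVector trilinear_resize_fw_cpp(NumericVector x, IntegerVector dimx,
                                      IntegerVector dimo) {
  const int C = dimx[0], H = dimx[1], W = dimx[2], D = dimx[3];
  const int Ho = dimo[0], Wo = dimo[1], Do = dimo[2];
  NumericVector y((size_t)C * Ho * Wo * Do);
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, Do);
  const double rh = (double)H / Ho, rw = (double)W / Wo, rd = (double)D / Do;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int dz = 0; dz < Do; ++dz) {
    double sz = (dz + 0.5) * rd - 0.5;
    if (sz < 0) sz = 0; if (sz > D - 1) sz = D - 1;
    const int z0 = (int)std::floor(sz), z1 = std::min(z0 + 1, D - 1);
    const double fz = sz - z0;
    for (int wy = 0; wy < Wo; ++wy) {
      double swc = (wy + 0.5) * rw - 0.5;
      if (swc < 0) swc = 0; if (swc > W - 1) swc = W - 1;
      const int w0 = (int)std::floor(swc), w1 = std::min(w0 + 1, W - 1);
      const double fw = swc - w0;
      for (int hy = 0; hy < Ho; ++hy) {
        double sh = (hy + 0.5) * rh - 0.5;
        if (sh < 0) sh = 0; if (sh > H - 1) sh = H - 1;
        const int h0 = (int)std::floor(sh), h1 = std::min(h0 + 1, H - 1);
        const double fh = sh - h0;
        double* dst = yp + (size_t)C * ((size_t)hy + (size_t)Ho * ((size_t)wy + (size_t)Wo * dz));
        for (int c = 0; c < C; ++c) {
          #define XAT(hh, ww, dd) xp[(size_t)c + (size_t)C * ((size_t)(hh) + (size_t)H * ((size_t)(ww) + (size_t)W * (dd)))]
          const double v =
            (1 - fz) * ((1 - fw) * ((1 - fh) * XAT(h0, w0, z0) + fh * XAT(h1, w0, z0)) +
                        fw       * ((1 - fh) * XAT(h0, w1, z0) + fh * XAT(h1, w1, z0))) +
            fz       * ((1 - fw) * ((1 - fh) * XAT(h0, w0, z1) + fh * XAT(h1, w0, z1)) +
                        fw       * ((1 - fh) * XAT(h0, w1, z1) + fh * XAT(h1, w1, z1)));
          #undef XAT
          dst[c] = v;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector trilinear_resize_bw_cpp(NumericVector gy, IntegerVector dimx,
                                      IntegerVector dimo) {
  const int C = dimx[0], H = dimx[1], W = dimx[2], D = dimx[3];
  const int Ho = dimo[0], Wo = dimo[1], Do = dimo[2];
  NumericVector gx((size_t)C * H * W * D);
  gx.attr("dim") = dimx;
  const double rh = (double)H / Ho, rw = (double)W / Wo, rd = (double)D / Do;
  const double* gyp = gy.begin();
  double* gxp = gx.begin();
  for (int dz = 0; dz < Do; ++dz) {
    double sz = (dz + 0.5) * rd - 0.5;
    if (sz < 0) sz = 0; if (sz > D - 1) sz = D - 1;
    const int z0 = (int)std::floor(sz), z1 = std::min(z0 + 1, D - 1);
    const double fz = sz - z0;
    for (int wy = 0; wy < Wo; ++wy) {
      double swc = (wy + 0.5) * rw - 0.5;
      if (swc < 0) swc = 0; if (swc > W - 1) swc = W - 1;
      const int w0 = (int)std::floor(swc), w1 = std::min(w0 + 1, W - 1);
      const double fw = swc - w0;
      for (int hy = 0; hy < Ho; ++hy) {
        double sh = (hy + 0.5) * rh - 0.5;
        if (sh < 0) sh = 0; if (sh > H - 1) sh = H - 1;
        const int h0 = (int)std::floor(sh), h1 = std::min(h0 + 1, H - 1);
        const double fh = sh - h0;
        const double* src = gyp + (size_t)C * ((size_t)hy + (size_t)Ho * ((size_t)wy + (size_t)Wo * dz));
        const double wts[8] = {
          (1 - fz) * (1 - fw) * (1 - fh), (1 - fz) * (1 - fw) * fh,
          (1 - fz) * fw * (1 - fh),       (1 - fz) * fw * fh,
          fz * (1 - fw) * (1 - fh),       fz * (1 - fw) * fh,
          fz * fw * (1 - fh),             fz * fw * fh };
        const int hs[8] = {h0, h1, h0, h1, h0, h1, h0, h1};
        const int ws_[8] = {w0, w0, w1, w1, w0, w0, w1, w1};
        const int zs[8] = {z0, z0, z0, z0, z1, z1, z1, z1};
        for (int k = 0; k < 8; ++k) {
          if (wts[k] == 0) continue;
          double* dst = gxp + (size_t)C * ((size_t)hs[k] + (size_t)H * ((size_t)ws_[k] + (size_t)W * zs[k]));
          for (int c = 0; c < C; ++c) dst[c] += wts[k] * src[c];
        }
      }
    }
  }
  return gx;
}

// Differentiable spatial warp of a single-channel volume.
// x: (H,W,D); disp: (3,H,W,D) with channels (dh, dw, dd) in voxel units.
// out(p) = trilinear sample of x at p + disp(p); samples outside the volume
// take `fill`.
// [[Rcpp::export]]
NumericVector warp_fw_cpp(NumericVector x, IntegerVector dimx,
                          NumericVector disp, double fill) {
  const int H = dimx[0], W = dimx[1], D = dimx[2];
  NumericVector y((size_t)H * W * D);
  y.attr("dim") = dimx;
  const double* xp = x.begin();
  const double* dp = disp.begin();
  double* yp = y.begin();
  for (int d = 0; d < D; ++d)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const size_t pi = (size_t)h + (size_t)H * ((size_t)w + (size_t)W * d);
        const double sh = h + dp[3 * pi + 0];
        const double sw = w + dp[3 * pi + 1];
        const double sd = d + dp[3 * pi + 2];
        if (sh < 0 || sh > H - 1 || sw < 0 || sw > W - 1 || sd < 0 || sd > D - 1) {
          yp[pi] = fill;
          continue;
        }
        const int h0 = (int)std::floor(sh), w0 = (int)std::floor(sw), d0 = (int)std::floor(sd);
        const int h1 = std::min(h0 + 1, H - 1), w1 = std::min(w0 + 1, W - 1), d1 = std::min(d0 + 1, D - 1);
        const double fh = sh - h0, fw = sw - w0, fd = sd - d0;
        #define XA(hh, ww, dd) xp[(size_t)(hh) + (size_t)H * ((size_t)(ww) + (size_t)W * (dd))]
        yp[pi] =
          (1 - fd) * ((1 - fw) * ((1 - fh) * XA(h0, w0, d0) + fh * XA(h1, w0, d0)) +
                      fw       * ((1 - fh) * XA(h0, w1, d0) + fh * XA(h1, w1, d0))) +
          fd       * ((1 - fw) * ((1 - fh) * XA(h0, w0, d1) + fh * XA(h1, w0, d1)) +
                      fw       * ((1 - fh) * XA(h0, w1, d1) + fh * XA(h1, w1, d1)));
        #undef XA
      }
  return y;
}

// Backward of warp_fw_cpp w.r.t. both the image and the displacement.
// [[Rcpp::export]]
List warp_bw_cpp(NumericVector x, IntegerVector dimx,
                 NumericVector disp, NumericVector gy) {
  const int H = dimx[0], W = dimx[1], D = dimx[2];
  NumericVector gx((size_t)H * W * D);
  gx.attr("dim") = dimx;
  NumericVector gd((size_t)3 * H * W * D);
  gd.attr("dim") = IntegerVector::create(3, H, W, D);
  const double* xp = x.begin();
  const double* dp = disp.begin();
  const double* gyp = gy.begin();
  double* gxp = gx.begin();
  double* gdp = gd.begin();
  for (int d = 0; d < D; ++d)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const size_t pi = (size_t)h + (size_t)H * ((size_t)w + (size_t)W * d);
        const double g = gyp[pi];
        if (g == 0) continue;
        const double sh = h + dp[3 * pi + 0];
        const double sw = w + dp[3 * pi + 1];
        const double sd = d + dp[3 * pi + 2];
        if (sh < 0 || sh > H - 1 || sw < 0 || sw > W - 1 || sd < 0 || sd > D - 1)
          continue;  // fill region: zero gradient
        const int h0 = (int)std::floor(sh), w0 = (int)std::floor(sw), d0 = (int)std::floor(sd);
        const int h1 = std::min(h0 + 1, H - 1), w1 = std::min(w0 + 1, W - 1), d1 = std::min(d0 + 1, D - 1);
        const double fh = sh - h0, fw = sw - w0, fd = sd - d0;
        #define XA(hh, ww, dd) xp[(size_t)(hh) + (size_t)H * ((size_t)(ww) + (size_t)W * (dd))]
        #define GXA(hh, ww, dd) gxp[(size_t)(hh) + (size_t)H * ((size_t)(ww) + (size_t)W * (dd))]
        const double c000 = XA(h0, w0, d0), c100 = XA(h1, w0, d0);
        const double c010 = XA(h0, w1, d0), c110 = XA(h1, w1, d0);
        const double c001 = XA(h0, w0, d1), c101 = XA(h1, w0, d1);
        const double c011 = XA(h0, w1, d1), c111 = XA(h1, w1, d1);
        // gradient to image corners
        GXA(h0, w0, d0) += g * (1 - fd) * (1 - fw) * (1 - fh);
        GXA(h1, w0, d0) += g * (1 - fd) * (1 - fw) * fh;
        GXA(h0, w1, d0) += g * (1 - fd) * fw * (1 - fh);
        GXA(h1, w1, d0) += g * (1 - fd) * fw * fh;
        GXA(h0, w0, d1) += g * fd * (1 - fw) * (1 - fh);
        GXA(h1, w0, d1) += g * fd * (1 - fw) * fh;
        GXA(h0, w1, d1) += g * fd * fw * (1 - fh);
        GXA(h1, w1, d1) += g * fd * fw * fh;
        // gradient to the sample coordinates = gradient to the displacement
        const double dh_ =
          (1 - fd) * ((1 - fw) * (c100 - c000) + fw * (c110 - c010)) +
          fd       * ((1 - fw) * (c101 - c001) + fw * (c111 - c011));
        const double dw_ =
          (1 - fd) * ((1 - fh) * (c010 - c000) + fh * (c110 - c100)) +
          fd       * ((1 - fh) * (c011 - c001) + fh * (c111 - c101));
        const double dd_ =
          (1 - fw) * ((1 - fh) * (c001 - c000) + fh * (c101 - c100)) +
          fw       * ((1 - fh) * (c011 - c010) + fh * (c111 - c110));
        gdp[3 * pi + 0] += g * dh_;
        gdp[3 * pi + 1] += g * dw_;
        gdp[3 * pi + 2] += g * dd_;
        #undef XA
        #undef GXA
      }
  return List::create(_["gx"] = gx, _["gdisp"] = gd);
}
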