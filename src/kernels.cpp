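// Low-level numeric kernels for the FCN layer stack and mask utilities.
// Tensors follow R's column-major layout: feature maps are (H, W, C) cubes,
// convolution weights are flattened (kh, kw, c_in, c_out) arrays.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Lay out every kh x kw x C receptive field of x (zero padded by `pad`)
// as one column; row index is a + kh*(b + kw*c), matching the R flatten
// order of a (kh, kw, C, ...) weight array.
static arma::mat im2col(const arma::cube& x, int kh, int kw, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  arma::mat cols(kh * kw * C, (arma::uword)Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        const int r = a + kh * (b + kw * c);
        for (int j = 0; j < Wo; ++j) {
          const int xj = j - pad + b;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int xi = i - pad + a;
            if (xi < 0 || xi >= H) continue;
            cols(r, (arma::uword)i + (arma::uword)Ho * j) = sl(xi, xj);
          }
        }
      }
    }
  }
  return cols;
}

// Stride-1 cross-correlation with zero padding: y[i,j,o] =
//   sum_{a,b,c} x[i-pad+a, j-pad+b, c] * w[a,b,c,o] + bias[o]
// [[Rcpp::export]]
arma::cube cf_conv2d_fwd(const arma::cube& x, const arma::vec& w,
                         int kh, int kw, int co,
                         const arma::vec& bias, int pad) {
  const int C = x.n_slices;
  const arma::mat Wm(const_cast<double*>(w.memptr()), kh * kw * C, co, false);
  const arma::mat cols = im2col(x, kh, kw, pad);
  const arma::mat y = Wm.t() * cols;  // co x (Ho*Wo)
  const int Ho = x.n_rows + 2 * pad - kh + 1;
  const int Wo = x.n_cols + 2 * pad - kw + 1;
  arma::cube out(Ho, Wo, co);
  for (int c = 0; c < co; ++c) {
    out.slice(c) = arma::reshape(y.row(c), Ho, Wo);
    out.slice(c) += bias(c);
  }
  return out;
}

// [[Rcpp::export]]
List cf_conv2d_bwd(const arma::cube& x, const arma::vec& w,
                   int kh, int kw, int co, const arma::cube& gy, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  const arma::mat Wm(const_cast<double*>(w.memptr()), kh * kw * C, co, false);
  const arma::mat cols = im2col(x, kh, kw, pad);
  arma::mat G((arma::uword)Ho * Wo, co);
  arma::vec gb(co);
  for (int c = 0; c < co; ++c) {
    G.col(c) = arma::vectorise(gy.slice(c));
    gb(c) = arma::accu(gy.slice(c));
  }
  const arma::mat gW = cols * G;        // (kh*kw*C) x co
  const arma::mat colg = Wm * G.t();    // (kh*kw*C) x (Ho*Wo)
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& gsl = gx.slice(c);
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        const int r = a + kh * (b + kw * c);
        for (int j = 0; j < Wo; ++j) {
          const int xj = j - pad + b;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int xi = i - pad + a;
            if (xi < 0 || xi >= H) continue;
            gsl(xi, xj) += colg(r, (arma::uword)i + (arma::uword)Ho * j);
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = arma::vectorise(gW),
                      _["gb"] = gb);
}

// Max pooling, ceil mode (partial windows at the border are allowed so no
// input pixel is dropped on odd extents). Returns pooled map and, per output
// cell, the 0-based linear index (i + H*j) of the winning input pixel.
// Ties go to the first pixel in column-major scan order.
// [[Rcpp::export]]
List cf_maxpool_fwd(const arma::cube& x, int k, int stride) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H <= k) ? 1 : (int)std::ceil((double)(H - k) / stride) + 1;
  const int Wo = (W <= k) ? 1 : (int)std::ceil((double)(W - k) / stride) + 1;
  arma::cube y(Ho, Wo, C);
  arma::cube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      const int j0 = j * stride, j1 = std::min(j0 + k, W);
      for (int i = 0; i < Ho; ++i) {
        const int i0 = i * stride, i1 = std::min(i0 + k, H);
        double best = -std::numeric_limits<double>::infinity();
        arma::uword bi = 0;
        for (int jj = j0; jj < j1; ++jj) {
          for (int ii = i0; ii < i1; ++ii) {
            const double v = x(ii, jj, c);
            if (v > best) {
              best = v;
              bi = (arma::uword)ii + (arma::uword)H * jj;
            }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = (double)bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cf_maxpool_bwd(const arma::cube& gy, const arma::cube& idx,
                          int H, int W) {
  const int C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* g = gx.slice_memptr(c);
    const arma::uword n = gy.n_rows * gy.n_cols;
    for (arma::uword q = 0; q < n; ++q) {
      g[(arma::uword)idx.slice(c)(q)] += gy.slice(c)(q);
    }
  }
  return gx;
}

// Transposed convolution ("deconvolution" / learned upsampling):
// y[i*stride - pad + a, j*stride - pad + b, o] += x[i,j,c] * w[a,b,c,o]
// Output extent is (n-1)*stride - 2*pad + k per spatial dim.
// [[Rcpp::export]]
arma::cube cf_deconv_fwd(const arma::cube& x, const arma::vec& w,
                         int kh, int kw, int co, int stride, int pad) {
  const int h = x.n_rows, wd = x.n_cols, ci = x.n_slices;
  const int Ho = (h - 1) * stride - 2 * pad + kh;
  const int Wo = (wd - 1) * stride - 2 * pad + kw;
  arma::cube y(Ho, Wo, co, arma::fill::zeros);
  for (int oc = 0; oc < co; ++oc) {
    for (int ic = 0; ic < ci; ++ic) {
      const arma::uword wbase = (arma::uword)kh * kw * (ic + (arma::uword)ci * oc);
      for (int j = 0; j < wd; ++j) {
        for (int i = 0; i < h; ++i) {
          const double v = x(i, j, ic);
          if (v == 0.0) continue;
          for (int b = 0; b < kw; ++b) {
            const int oj = j * stride - pad + b;
            if (oj < 0 || oj >= Wo) continue;
            for (int a = 0; a < kh; ++a) {
              const int oi = i * stride - pad + a;
              if (oi < 0 || oi >= Ho) continue;
              y(oi, oj, oc) += v * w[wbase + a + (arma::uword)kh * b];
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cf_deconv_bwd(const arma::cube& x, const arma::vec& w,
                   int kh, int kw, int co, int stride, int pad,
                   const arma::cube& gy) {
  const int h = x.n_rows, wd = x.n_cols, ci = x.n_slices;
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  arma::cube gx(h, wd, ci, arma::fill::zeros);
  arma::vec gw(w.n_elem, arma::fill::zeros);
  for (int oc = 0; oc < co; ++oc) {
    for (int ic = 0; ic < ci; ++ic) {
      const arma::uword wbase = (arma::uword)kh * kw * (ic + (arma::uword)ci * oc);
      for (int j = 0; j < wd; ++j) {
        for (int i = 0; i < h; ++i) {
          const double v = x(i, j, ic);
          double acc = 0.0;
          for (int b = 0; b < kw; ++b) {
            const int oj = j * stride - pad + b;
            if (oj < 0 || oj >= Wo) continue;
            for (int a = 0; a < kh; ++a) {
              const int oi = i * stride - pad + a;
              if (oi < 0 || oi >= Ho) continue;
              const double g = gy(oi, oj, oc);
              acc += g * w[wbase + a + (arma::uword)kh * b];
              gw[wbase + a + (arma::uword)kh * b] += v * g;
            }
          }
          gx(i, j, ic) += acc;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// Connected-component labeling of a binary mask; connectivity 4 or 8.
// Labels are 1..n in column-major discovery order.
// [[Rcpp::export]]
IntegerMatrix cf_label_components(const IntegerMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + H * j);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int d = 0; d < nn; ++d) {
          const int ni = pi + di[d], nj = pj + dj[d];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + H * nj);
          }
        }
      }
    }
  }
  return lab;
}

// Euclidean distance (in pixels) from each query point (0-based row/col)
// to the nearest foreground pixel centre; Inf when the mask is empty.
// [[Rcpp::export]]
NumericVector cf_min_dist_to_mask(const IntegerMatrix& mask,
                                  const NumericVector& rows,
                                  const NumericVector& cols) {
  std::vector<double> fi, fj;
  for (int j = 0; j < mask.ncol(); ++j) {
    for (int i = 0; i < mask.nrow(); ++i) {
      if (mask(i, j) != 0) {
        fi.push_back((double)i);
        fj.push_back((double)j);
      }
    }
  }
  const int n = rows.size();
  NumericVector out(n);
  for (int c = 0; c < n; ++c) {
    double best = R_PosInf;
    for (size_t q = 0; q < fi.size(); ++q) {
      const double d = (rows[c] - fi[q]) * (rows[c] - fi[q]) +
                       (cols[c] - fj[q]) * (cols[c] - fj[q]);
      if (d < best) best = d;
    }
    out[c] = std::sqrt(best);
  }
  return out;
}
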