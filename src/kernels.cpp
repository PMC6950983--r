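// Low-level CPU kernels for the segmentation network engine.
// Tensors cross the R boundary as double (H, W, C) arrays; convolution
// arithmetic runs in single precision internally (the usual CNN training
// precision), which halves memory traffic on the large im2col buffers.
// Convolution weights are matrices of shape (k*k*Cin) x Cout with patch
// entries ordered channel-major (ch, then kernel column, then kernel row),
// matching im2col() below.
#include <RcppArmadillo.h>
#include <functional>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int H, int k, int stride, int pt, int pb) {
  return (H + pt + pb - k) / stride + 1;
}

// Valid output index range [lo, hi) for which s = i*stride + d - p is in
// [0, n).
static inline void valid_range(int n, int no, int stride, int d, int p,
                               int& lo, int& hi) {
  lo = 0;
  while (lo < no && lo * stride + d - p < 0) ++lo;
  hi = no;
  while (hi > lo && (hi - 1) * stride + d - p >= n) --hi;
}

static arma::fmat im2col_f(const arma::cube& x, int k, int stride,
                           int pt, int pl, int pb, int pr) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_size(H, k, stride, pt, pb);
  const int Wo = out_size(W, k, stride, pl, pr);
  arma::fmat cols(Ho * (arma::uword)Wo, (arma::uword)k * k * C,
                  arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    const arma::mat& sl = x.slice(ch);
    for (int dx = 0; dx < k; ++dx) {
      int clo, chi;
      valid_range(W, Wo, stride, dx, pl, clo, chi);
      for (int dy = 0; dy < k; ++dy) {
        int rlo, rhi;
        valid_range(H, Ho, stride, dy, pt, rlo, rhi);
        const int colidx = ch * k * k + dx * k + dy;
        float* dst = cols.colptr(colidx);
        for (int c = clo; c < chi; ++c) {
          const double* src = sl.colptr(c * stride + dx - pl) - pt + dy;
          float* d0 = dst + (arma::uword)c * Ho;
          if (stride == 1) {
            for (int r = rlo; r < rhi; ++r) d0[r] = (float)src[r];
          } else {
            for (int r = rlo; r < rhi; ++r) d0[r] = (float)src[r * stride];
          }
        }
      }
    }
  }
  return cols;
}

static arma::cube col2im_f(const arma::fmat& cols, int H, int W, int C,
                           int k, int stride, int pt, int pl, int pb, int pr) {
  const int Ho = out_size(H, k, stride, pt, pb);
  const int Wo = out_size(W, k, stride, pl, pr);
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    arma::mat& sl = x.slice(ch);
    for (int dx = 0; dx < k; ++dx) {
      int clo, chi;
      valid_range(W, Wo, stride, dx, pl, clo, chi);
      for (int dy = 0; dy < k; ++dy) {
        int rlo, rhi;
        valid_range(H, Ho, stride, dy, pt, rlo, rhi);
        const int colidx = ch * k * k + dx * k + dy;
        const float* src = cols.colptr(colidx);
        for (int c = clo; c < chi; ++c) {
          double* dst = sl.colptr(c * stride + dx - pl) - pt + dy;
          const float* s0 = src + (arma::uword)c * Ho;
          if (stride == 1) {
            for (int r = rlo; r < rhi; ++r) dst[r] += s0[r];
          } else {
            for (int r = rlo; r < rhi; ++r) dst[r * stride] += s0[r];
          }
        }
      }
    }
  }
  return x;
}

static arma::fmat to_f(const arma::mat& a) {
  return arma::conv_to<arma::fmat>::from(a);
}

static arma::fmat cube_mat_f(const arma::cube& a) {
  arma::fmat out(a.n_rows * a.n_cols, a.n_slices);
  const double* src = a.memptr();
  float* dst = out.memptr();
  const arma::uword n = a.n_elem;
  for (arma::uword i = 0; i < n; ++i) dst[i] = (float)src[i];
  return out;
}

static arma::cube fmat_cube(const arma::fmat& m, int H, int W, int C) {
  arma::cube out(H, W, C);
  const float* src = m.memptr();
  double* dst = out.memptr();
  const arma::uword n = out.n_elem;
  for (arma::uword i = 0; i < n; ++i) dst[i] = (double)src[i];
  return out;
}

// Standard convolution, 'same'-style padding supplied by caller.
// [[Rcpp::export]]
arma::cube conv_fwd(const arma::cube& x, const arma::mat& Wm, const arma::vec& b,
                    int k, int stride, int pt, int pl, int pb, int pr) {
  const int Ho = out_size(x.n_rows, k, stride, pt, pb);
  const int Wo = out_size(x.n_cols, k, stride, pl, pr);
  arma::fmat cols = im2col_f(x, k, stride, pt, pl, pb, pr);
  arma::fmat out = cols * to_f(Wm);
  out.each_row() += to_f(b.t());
  return fmat_cube(out, Ho, Wo, Wm.n_cols);
}

// [[Rcpp::export]]
List conv_bwd(const arma::cube& x, const arma::mat& Wm, const arma::cube& gy,
              int k, int stride, int pt, int pl, int pb, int pr) {
  arma::fmat gy_mat = cube_mat_f(gy);
  arma::fmat cols = im2col_f(x, k, stride, pt, pl, pb, pr);
  arma::fmat gW = cols.t() * gy_mat;
  arma::fvec gb = arma::sum(gy_mat, 0).t();
  arma::fmat gcols = gy_mat * to_f(Wm).t();
  arma::cube gx = col2im_f(gcols, x.n_rows, x.n_cols, x.n_slices,
                           k, stride, pt, pl, pb, pr);
  return List::create(
    _["gx"] = gx,
    _["gW"] = arma::conv_to<arma::mat>::from(gW),
    _["gb"] = arma::conv_to<arma::vec>::from(gb));
}

// Transposed convolution, stride 2, 'same' output size 2H x 2W.  Weights
// are stored as the adjoint convolution's matrix: (k*k*F) x Cin.
// [[Rcpp::export]]
arma::cube tconv_fwd(const arma::cube& x, const arma::mat& Wm, const arma::vec& b,
                     int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int F = Wm.n_rows / (k * k);
  const int pb = (k == 3) ? 1 : 0, pr = pb;
  arma::fmat x_mat = cube_mat_f(x);
  arma::fmat cols = x_mat * to_f(Wm).t();
  arma::cube y = col2im_f(cols, 2 * H, 2 * W, F, k, 2, 0, 0, pb, pr);
  for (int f = 0; f < F; ++f) y.slice(f) += b(f);
  return y;
}

// [[Rcpp::export]]
List tconv_bwd(const arma::cube& x, const arma::mat& Wm, const arma::cube& gy,
               int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int F = gy.n_slices;
  const int pb = (k == 3) ? 1 : 0, pr = pb;
  arma::fmat x_mat = cube_mat_f(x);
  arma::fmat gcols = im2col_f(gy, k, 2, 0, 0, pb, pr);  // (H*W) x (k*k*F)
  arma::fmat gW = gcols.t() * x_mat;
  arma::fmat gx_mat = gcols * to_f(Wm);
  arma::vec gb(F);
  for (int f = 0; f < F; ++f) gb(f) = arma::accu(gy.slice(f));
  return List::create(
    _["gx"] = fmat_cube(gx_mat, H, W, Cin),
    _["gW"] = arma::conv_to<arma::mat>::from(gW),
    _["gb"] = gb);
}

// Per-channel sums and sums of squares (batch-norm statistics) without
// intermediate copies.
// [[Rcpp::export]]
List channel_sums(const arma::cube& z) {
  const int C = z.n_slices;
  arma::vec s(C), s2(C);
  for (int ch = 0; ch < C; ++ch) {
    const arma::mat& sl = z.slice(ch);
    s(ch) = arma::accu(sl);
    s2(ch) = arma::dot(arma::vectorise(sl), arma::vectorise(sl));
  }
  return List::create(_["s"] = s, _["s2"] = s2);
}

// Fused per-channel affine map plus activation: y = act(a*z + b).
// act: 0 = linear, 1 = relu, 2 = sigmoid.
// [[Rcpp::export]]
arma::cube bn_act_fwd(const arma::cube& z, const arma::vec& a,
                      const arma::vec& b, int act) {
  arma::cube y(z.n_rows, z.n_cols, z.n_slices);
  const arma::uword HW = z.n_rows * z.n_cols;
  for (arma::uword ch = 0; ch < z.n_slices; ++ch) {
    const double ai = a(ch), bi = b(ch);
    const double* src = z.slice(ch).memptr();
    double* dst = y.slice(ch).memptr();
    switch (act) {
    case 1:
      for (arma::uword i = 0; i < HW; ++i) {
        const double v = ai * src[i] + bi;
        dst[i] = v > 0 ? v : 0;
      }
      break;
    case 2:
      for (arma::uword i = 0; i < HW; ++i)
        dst[i] = 1.0 / (1.0 + std::exp(-(ai * src[i] + bi)));
      break;
    default:
      for (arma::uword i = 0; i < HW; ++i) dst[i] = ai * src[i] + bi;
    }
  }
  return y;
}

// Backward of relu-after-batch-norm, pass 1: mask the incoming gradient by
// the relu derivative and accumulate the per-channel sums needed for the
// batch-norm gradient (sum of g_eff and of g_eff * x-hat).
// [[Rcpp::export]]
List bn_relu_bwd_stats(const arma::cube& g, const arma::cube& y,
                       const arma::cube& z, const arma::vec& m,
                       const arma::vec& invstd, bool relu) {
  const int C = g.n_slices;
  const arma::uword HW = g.n_rows * g.n_cols;
  arma::cube geff(g.n_rows, g.n_cols, C);
  arma::vec sg(C), sgx(C);
  for (int ch = 0; ch < C; ++ch) {
    const double* gp = g.slice(ch).memptr();
    const double* yp = y.slice(ch).memptr();
    const double* zp = z.slice(ch).memptr();
    double* ge = geff.slice(ch).memptr();
    const double mi = m(ch), isd = invstd(ch);
    double a1 = 0, a2 = 0;
    for (arma::uword i = 0; i < HW; ++i) {
      const double gi = relu ? (yp[i] > 0 ? gp[i] : 0.0) : gp[i];
      ge[i] = gi;
      a1 += gi;
      a2 += gi * (zp[i] - mi) * isd;
    }
    sg(ch) = a1;
    sgx(ch) = a2;
  }
  return List::create(_["geff"] = geff, _["sg"] = sg, _["sgx"] = sgx);
}

// Backward of batch-norm, pass 2: gradient w.r.t. the pre-normalisation
// activations given the batch-wide correction terms c1, c2.
// [[Rcpp::export]]
arma::cube bn_bwd_gz(const arma::cube& geff, const arma::cube& z,
                     const arma::vec& gamma, const arma::vec& m,
                     const arma::vec& invstd, const arma::vec& c1,
                     const arma::vec& c2) {
  const int C = geff.n_slices;
  const arma::uword HW = geff.n_rows * geff.n_cols;
  arma::cube gz(geff.n_rows, geff.n_cols, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* ge = geff.slice(ch).memptr();
    const double* zp = z.slice(ch).memptr();
    double* out = gz.slice(ch).memptr();
    const double gi = gamma(ch), mi = m(ch), isd = invstd(ch);
    const double c1i = c1(ch), c2i = c2(ch);
    for (arma::uword i = 0; i < HW; ++i)
      out[i] = isd * (ge[i] * gi - c1i - (zp[i] - mi) * isd * c2i);
  }
  return gz;
}

// 2x2 max pooling, stride 2 (even H, W).
// [[Rcpp::export]]
List maxpool_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  for (int ch = 0; ch < C; ++ch) {
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        double best = x(2 * r, 2 * c, ch);
        unsigned which = 0;
        const double cand1 = x(2 * r + 1, 2 * c, ch);
        const double cand2 = x(2 * r, 2 * c + 1, ch);
        const double cand3 = x(2 * r + 1, 2 * c + 1, ch);
        if (cand1 > best) { best = cand1; which = 1; }
        if (cand2 > best) { best = cand2; which = 2; }
        if (cand3 > best) { best = cand3; which = 3; }
        y(r, c, ch) = best;
        idx(r, c, ch) = which;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool_bwd(const arma::cube& gy, const arma::ucube& idx,
                       int H, int W) {
  const int C = gy.n_slices, Ho = gy.n_rows, Wo = gy.n_cols;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        const unsigned w = idx(r, c, ch);
        gx(2 * r + (w == 1 || w == 3), 2 * c + (w == 2 || w == 3), ch) +=
          gy(r, c, ch);
      }
    }
  }
  return gx;
}

// Nearest-neighbour 2x upsampling (repeat rows and columns).
// [[Rcpp::export]]
arma::cube upsample_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        const double v = x(r, c, ch);
        y(2 * r, 2 * c, ch) = v;
        y(2 * r + 1, 2 * c, ch) = v;
        y(2 * r, 2 * c + 1, ch) = v;
        y(2 * r + 1, 2 * c + 1, ch) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube upsample_bwd(const arma::cube& gy) {
  const int H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  arma::cube gx(H, W, C);
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        gx(r, c, ch) = gy(2 * r, 2 * c, ch) + gy(2 * r + 1, 2 * c, ch) +
          gy(2 * r, 2 * c + 1, ch) + gy(2 * r + 1, 2 * c + 1, ch);
  return gx;
}

// Connected-component labelling with 4- or 8-connectivity (union-find).
// Components are numbered 1..K in order of first appearance in column-major
// scan; 0 stays background.
// [[Rcpp::export]]
IntegerMatrix cc_label(const IntegerMatrix& mask, int conn) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<int> parent(1, 0);
  std::vector<int> lab((size_t)H * W, 0);
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0) continue;
      const size_t i = (size_t)c * H + r;
      int up = (r > 0 && mask(r - 1, c)) ? lab[i - 1] : 0;
      int left = (c > 0 && mask(r, c - 1)) ? lab[i - H] : 0;
      int ul = 0, dl = 0;
      if (conn == 8 && c > 0) {
        if (r > 0 && mask(r - 1, c - 1)) ul = lab[i - H - 1];
        if (r < H - 1 && mask(r + 1, c - 1)) dl = lab[i - H + 1];
      }
      int cur = 0;
      for (int nb : {up, left, ul, dl})
        if (nb) cur = cur ? std::min(cur, nb) : nb;
      if (!cur) {
        cur = ++next;
        parent.push_back(cur);
      } else {
        for (int nb : {up, left, ul, dl}) if (nb) unite(cur, nb);
      }
      lab[i] = cur;
    }
  }
  std::vector<int> remap(next + 1, 0);
  int K = 0;
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      const size_t i = (size_t)c * H + r;
      if (!lab[i]) continue;
      const int root = find(lab[i]);
      if (!remap[root]) remap[root] = ++K;
      out(r, c) = remap[root];
    }
  return out;
}
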