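// Compact CPU U-Net: 3x3 same-padding convolutions via im2col + GEMM,
// 2x2 max pooling, nearest-neighbour upsampling, skip concatenation and a
// 1x1 output head. Forward + analytic backward for a dice+BCE loss on a
// single-channel probability map. Weights travel as a flat R list of
// (matrix, bias) pairs in forward order so models serialize with saveRDS.

#include <RcppArmadillo.h>
#include <deque>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Reusable buffer arena: the layer sequence (and hence the buffer-size
// sequence) is identical on every call, so each slot keeps its allocation
// across images and avoids re-faulting hundreds of MB per training step.
static std::deque<mat>& arena() {
  static std::deque<mat> pool;  // deque: references stay valid on growth
  return pool;
}
static size_t arena_cursor = 0;
static mat& grab(size_t nr, size_t nc) {
  std::deque<mat>& pool = arena();
  if (arena_cursor == pool.size()) pool.emplace_back();
  mat& m = pool[arena_cursor++];
  m.set_size(nr, nc);
  return m;
}

// Patch matrix layout: K is (H*W) x (k*k*C); column r = (c*k + dy)*k + dx
// holds the shifted image plane, so fills and reads are contiguous in y.
// Every element of K is written exactly once (borders get zeros).
static void im2col(const cube& x, int k, mat& K) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, pad = k / 2;
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int dy = 0; dy < k; ++dy) {
      for (int dx = 0; dx < k; ++dx) {
        const int r = (c * k + dy) * k + dx;
        const int oy = dy - pad, ox = dx - pad;
        const int y0 = std::max(0, -oy), y1 = std::min(H, H - oy);
        double* Kcol = K.colptr(r);
        for (int xc = 0; xc < W; ++xc) {
          const int sx = xc + ox;
          double* dst = Kcol + (size_t)xc * H;
          if (sx < 0 || sx >= W) {
            std::memset(dst, 0, sizeof(double) * H);
            continue;
          }
          const double* src = xs.colptr(sx) + oy;
          for (int y = 0; y < y0; ++y) dst[y] = 0.0;
          for (int y = y0; y < y1; ++y) dst[y] = src[y];
          for (int y = y1; y < H; ++y) dst[y] = 0.0;
        }
      }
    }
  }
}

static void col2im_acc(const mat& dK, int H, int W, int C, int k, cube& dx) {
  const int pad = k / 2;
  dx.zeros(H, W, C);
  for (int c = 0; c < C; ++c) {
    mat& xs = dx.slice(c);
    for (int dy = 0; dy < k; ++dy) {
      for (int dx_ = 0; dx_ < k; ++dx_) {
        const int r = (c * k + dy) * k + dx_;
        const int oy = dy - pad, ox = dx_ - pad;
        const int y0 = std::max(0, -oy), y1 = std::min(H, H - oy);
        const double* Kcol = dK.colptr(r);
        for (int xc = 0; xc < W; ++xc) {
          const int sx = xc + ox;
          if (sx < 0 || sx >= W) continue;
          double* dst = xs.colptr(sx) + oy;
          const double* src = Kcol + (size_t)xc * H;
          for (int y = y0; y < y1; ++y) dst[y] += src[y];
        }
      }
    }
  }
}

static cube conv_fwd(const cube& x, const mat& Wm, const vec& b, int k,
                     bool relu) {
  const int H = x.n_rows, W = x.n_cols, Cout = Wm.n_rows;
  mat& K = grab(H * W, k * k * x.n_slices);
  im2col(x, k, K);
  cube o(H, W, Cout);
  mat out(o.memptr(), (size_t)H * W, Cout, false, true);  // alias
  out = K * Wm.t();
  for (int co = 0; co < Cout; ++co) out.col(co) += b(co);
  if (relu) out.transform([](double v) { return v > 0 ? v : 0.0; });
  return o;
}

static cube conv_bwd(const cube& x_in, const mat& Wm, const cube& out,
                     const cube& dout_in, int k, bool relu, mat& dW,
                     vec& db) {
  const int H = x_in.n_rows, W = x_in.n_cols, Cin = x_in.n_slices;
  const int Cout = Wm.n_rows;
  // view dout (and the relu mask) as (HW x Cout)
  mat& dom = grab((size_t)H * W, Cout);
  std::memcpy(dom.memptr(), dout_in.memptr(),
              sizeof(double) * dout_in.n_elem);
  if (relu) {
    const double* op = out.memptr();
    double* dp = dom.memptr();
    for (size_t i = 0; i < dom.n_elem; ++i)
      if (op[i] <= 0) dp[i] = 0.0;
  }
  mat& K = grab((size_t)H * W, k * k * Cin);
  im2col(x_in, k, K);
  dW = dom.t() * K;
  db = sum(dom, 0).t();
  mat& dK = K;  // K is dead after dW; reuse its buffer for dom * Wm
  dK = dom * Wm;  // (HW x kkCin)
  cube dx;
  col2im_acc(dK, H, W, Cin, k, dx);
  return dx;
}

static cube pool_fwd(const cube& x, ucube& idx) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  cube o(H, W, C);
  idx.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int xc = 0; xc < W; ++xc)
      for (int y = 0; y < H; ++y) {
        double best = x(2 * y, 2 * xc, c);
        unsigned bi = 0;
        const int dy[4] = {0, 1, 0, 1}, dx[4] = {0, 0, 1, 1};
        for (unsigned q = 1; q < 4; ++q) {
          double v = x(2 * y + dy[q], 2 * xc + dx[q], c);
          if (v > best) { best = v; bi = q; }
        }
        o(y, xc, c) = best;
        idx(y, xc, c) = bi;
      }
  return o;
}

static cube pool_bwd(const cube& dout, const ucube& idx) {
  const int H = dout.n_rows, W = dout.n_cols, C = dout.n_slices;
  cube dx(2 * H, 2 * W, C, fill::zeros);
  const int dy[4] = {0, 1, 0, 1}, dxo[4] = {0, 0, 1, 1};
  for (int c = 0; c < C; ++c)
    for (int xc = 0; xc < W; ++xc)
      for (int y = 0; y < H; ++y) {
        const unsigned q = idx(y, xc, c);
        dx(2 * y + dy[q], 2 * xc + dxo[q], c) = dout(y, xc, c);
      }
  return dx;
}

static cube up_fwd(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube o(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int xc = 0; xc < W; ++xc)
      for (int y = 0; y < H; ++y) {
        const double v = x(y, xc, c);
        o(2 * y, 2 * xc, c) = v;
        o(2 * y + 1, 2 * xc, c) = v;
        o(2 * y, 2 * xc + 1, c) = v;
        o(2 * y + 1, 2 * xc + 1, c) = v;
      }
  return o;
}

static cube up_bwd(const cube& dout) {
  const int H = dout.n_rows / 2, W = dout.n_cols / 2, C = dout.n_slices;
  cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int xc = 0; xc < W; ++xc)
      for (int y = 0; y < H; ++y)
        dx(y, xc, c) = dout(2 * y, 2 * xc, c) + dout(2 * y + 1, 2 * xc, c) +
                       dout(2 * y, 2 * xc + 1, c) +
                       dout(2 * y + 1, 2 * xc + 1, c);
  return dx;
}

// Runs the net. conv_in / conv_out / pool indices are kept when `train`.
struct FwdState {
  std::vector<cube> conv_in, conv_out, skips;
  std::vector<ucube> pool_idx;
  mat z;
};

static void run_forward(const Rcpp::List& weights, const cube& x, int depth,
                        bool train, FwdState& st) {
  int wi = 0;
  auto getW = [&](int i) { return Rcpp::as<mat>(weights[2 * i]); };
  auto getB = [&](int i) { return Rcpp::as<vec>(weights[2 * i + 1]); };
  auto conv = [&](const cube& in, int k, bool relu) {
    mat Wm = getW(wi);
    vec b = getB(wi);
    ++wi;
    cube out = conv_fwd(in, Wm, b, k, relu);
    if (train) { st.conv_in.push_back(in); st.conv_out.push_back(out); }
    return out;
  };
  cube h = x;
  for (int l = 0; l < depth; ++l) {
    h = conv(h, 3, true);
    h = conv(h, 3, true);
    st.skips.push_back(h);
    ucube idx;
    h = pool_fwd(h, idx);
    if (train) st.pool_idx.push_back(idx);
  }
  h = conv(h, 3, true);
  h = conv(h, 3, true);
  for (int l = depth - 1; l >= 0; --l) {
    cube u = up_fwd(h);
    h = join_slices(u, st.skips[l]);
    h = conv(h, 3, true);
    h = conv(h, 3, true);
  }
  cube zc = conv(h, 1, false);
  st.z = zc.slice(0);
}

// [[Rcpp::export]]
arma::mat unet_predict_cpp(Rcpp::List weights, arma::cube x, int depth) {
  arena_cursor = 0;
  FwdState st;
  run_forward(weights, x, depth, false, st);
  return 1.0 / (1.0 + exp(-st.z));
}

// Forward + dice+BCE loss + full backward for one image.
// g is the 0/1 ground-truth matrix; returns gradients in weight order.
// [[Rcpp::export]]
Rcpp::List unet_train_step_cpp(Rcpp::List weights, arma::cube x, arma::mat g,
                               int depth, double w_bce, double w_dice) {
  arena_cursor = 0;
  FwdState st;
  run_forward(weights, x, depth, true, st);
  const mat& z = st.z;
  const double N = z.n_elem;
  mat p = 1.0 / (1.0 + exp(-z));

  // numerically stable BCE: softplus(z) - g*z, with a capped positive-class
  // weight against the strong background/foreground imbalance (keeps the
  // optimiser out of the all-background basin, where the dice gradient
  // vanishes with the saturating sigmoid)
  const double nfg = accu(g);
  const double wpos = nfg > 0 ? std::min(10.0, (N - nfg) / nfg) : 1.0;
  mat wpix = 1.0 + (wpos - 1.0) * g;
  const double wsum = accu(wpix);
  mat sp = z;
  sp.transform([](double v) {
    return (v > 0 ? v : 0.0) + std::log1p(std::exp(-std::fabs(v)));
  });
  const double bce = accu(wpix % (sp - g % z)) / wsum;

  const double eps = 1.0;
  const double inter = accu(p % g), denom = accu(p) + accu(g) + eps;
  const double dice_soft = (2.0 * inter + eps) / denom;

  // d(1-D)/dp = -(2 g denom - (2 inter + eps)) / denom^2
  mat ddice_dp = -(2.0 * g * denom - (2.0 * inter + eps)) / (denom * denom);
  mat dz = w_bce * (wpix % (p - g)) / wsum +
           w_dice * (ddice_dp % (p % (1.0 - p)));

  const int nconv = 4 * depth + 3;
  std::vector<mat> dWs(nconv);
  std::vector<vec> dbs(nconv);
  auto getW = [&](int i) { return Rcpp::as<mat>(weights[2 * i]); };

  int ci = nconv - 1;  // conv index, walking backwards
  // output 1x1 conv
  cube dzc(z.n_rows, z.n_cols, 1);
  dzc.slice(0) = dz;
  cube dh = conv_bwd(st.conv_in[ci], getW(ci), st.conv_out[ci], dzc, 1, false,
                     dWs[ci], dbs[ci]);
  --ci;
  // decoder stages, reverse of forward: l = 0 .. depth-1
  std::vector<cube> dskip(depth);
  for (int l = 0; l < depth; ++l) {
    dh = conv_bwd(st.conv_in[ci], getW(ci), st.conv_out[ci], dh, 3, true,
                  dWs[ci], dbs[ci]);
    --ci;
    cube dcat = conv_bwd(st.conv_in[ci], getW(ci), st.conv_out[ci], dh, 3,
                         true, dWs[ci], dbs[ci]);
    --ci;
    const int cskip = st.skips[l].n_slices;
    const int cup = dcat.n_slices - cskip;
    dskip[l] = dcat.slices(cup, dcat.n_slices - 1);
    dh = up_bwd(dcat.slices(0, cup - 1));
  }
  // bottleneck
  for (int q = 0; q < 2; ++q) {
    dh = conv_bwd(st.conv_in[ci], getW(ci), st.conv_out[ci], dh, 3, true,
                  dWs[ci], dbs[ci]);
    --ci;
  }
  // encoder stages, l = depth-1 .. 0
  for (int l = depth - 1; l >= 0; --l) {
    cube dc2 = pool_bwd(dh, st.pool_idx[l]);
    dc2 += dskip[l];
    dh = conv_bwd(st.conv_in[ci], getW(ci), st.conv_out[ci], dc2, 3, true,
                  dWs[ci], dbs[ci]);
    --ci;
    dh = conv_bwd(st.conv_in[ci], getW(ci), st.conv_out[ci], dh, 3, true,
                  dWs[ci], dbs[ci]);
    --ci;
  }

  Rcpp::List grads(2 * nconv);
  for (int i = 0; i < nconv; ++i) {
    grads[2 * i] = dWs[i];
    grads[2 * i + 1] = dbs[i];
  }
  return Rcpp::List::create(Rcpp::Named("grads") = grads,
                            Rcpp::Named("loss") = w_bce * bce +
                                                  w_dice * (1.0 - dice_soft),
                            Rcpp::Named("bce") = bce,
                            Rcpp::Named("diceSoft") = dice_soft);
}
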