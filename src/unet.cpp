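// U-Net engine: forward pass, backpropagation and losses for the
// encoder-decoder used by build_unet()/train().
//
// Conventions (must match R/unet.R):
//   feature maps  : fcube(H, W, C), column-major per slice
//   3x3 conv      : weight cube(Cin, Cout, 9), slice k -> offset dy = k/3 - 1,
//                   dx = k%3 - 1 (zero padded, stride 1)
//   2x2 up-conv   : weight cube(Cin, Cout, 4), slice k -> dy = k/2, dx = k%2
//                   (transposed conv, stride 2)
//   1x1 conv      : weight cube(Cin, 1, 1)
//   params list   : flat, pairs (W, b) in fixed order: encoder levels
//                   (2 convs each), bottleneck (2 convs), decoder levels
//                   deepest-first (up-conv, 2 convs), final 1x1 conv.
//   concatenation : [up-conv output, encoder skip] along the channel axis.
//
// Arithmetic is single precision (the standard for network training);
// parameters arrive as R doubles, are converted once per call, and
// gradients are accumulated in single precision and written back as
// doubles.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;

namespace {

fcube as_fcube(NumericVector v) {
  Rcpp::IntegerVector d = v.attr("dim");
  cube c(v.begin(), d[0], d[1], d.size() > 2 ? d[2] : 1, false, true);
  return conv_to<fcube>::from(c);
}
fvec as_fvec(NumericVector v) {
  vec x(v.begin(), v.size(), false, true);
  return conv_to<fvec>::from(x);
}
fmat as_fmat(NumericMatrix m) {
  mat x(m.begin(), m.nrow(), m.ncol(), false, true);
  return conv_to<fmat>::from(x);
}

struct Conv {
  fcube W;
  fvec b;
  fcube gW;  // same shape as W, zero-initialized
  fvec gb;
};

// ---- 3x3 same conv ---------------------------------------------------------

fcube conv3_forward(const fcube& in, const Conv& L) {
  const uword H = in.n_rows, W = in.n_cols, Cin = in.n_slices, Cout = L.W.n_cols;
  fcube out(H, W, Cout, fill::zeros);
  fmat outm(out.memptr(), H * W, Cout, false, true);
  fcube shifted(H, W, Cin);
  for (int k = 0; k < 9; ++k) {
    const int dy = k / 3 - 1, dx = k % 3 - 1;
    const uword i0 = std::max(0, -dy), i1 = H - 1 - std::max(0, dy);
    const uword j0 = std::max(0, -dx), j1 = W - 1 - std::max(0, dx);
    shifted.zeros();
    shifted.subcube(i0, j0, 0, i1, j1, Cin - 1) =
        in.subcube(i0 + dy, j0 + dx, 0, i1 + dy, j1 + dx, Cin - 1);
    fmat sm(shifted.memptr(), H * W, Cin, false, true);
    outm += sm * L.W.slice(k);
  }
  outm.each_row() += L.b.t();
  return out;
}

fcube conv3_backward(const fcube& in, Conv& L, fcube& dOut) {
  const uword H = in.n_rows, W = in.n_cols, Cin = in.n_slices;
  fmat dOutm(dOut.memptr(), H * W, dOut.n_slices, false, true);
  fcube dIn(H, W, Cin, fill::zeros);
  fcube shifted(H, W, Cin);
  for (int k = 0; k < 9; ++k) {
    const int dy = k / 3 - 1, dx = k % 3 - 1;
    const uword i0 = std::max(0, -dy), i1 = H - 1 - std::max(0, dy);
    const uword j0 = std::max(0, -dx), j1 = W - 1 - std::max(0, dx);
    shifted.zeros();
    shifted.subcube(i0, j0, 0, i1, j1, Cin - 1) =
        in.subcube(i0 + dy, j0 + dx, 0, i1 + dy, j1 + dx, Cin - 1);
    fmat sm(shifted.memptr(), H * W, Cin, false, true);
    L.gW.slice(k) += sm.t() * dOutm;
    fmat dSm = dOutm * L.W.slice(k).t();
    fcube dS(dSm.memptr(), H, W, Cin, false, true);
    dIn.subcube(i0 + dy, j0 + dx, 0, i1 + dy, j1 + dx, Cin - 1) +=
        dS.subcube(i0, j0, 0, i1, j1, Cin - 1);
  }
  L.gb += sum(dOutm, 0).t();
  return dIn;
}

// ---- 2x2 max pooling -------------------------------------------------------

fcube pool_forward(const fcube& in, ucube& argmax) {
  const uword H2 = in.n_rows / 2, W2 = in.n_cols / 2, C = in.n_slices;
  fcube out(H2, W2, C);
  argmax.set_size(H2, W2, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W2; ++j)
      for (uword i = 0; i < H2; ++i) {
        float best = -datum::inf;
        uword bk = 0;
        for (uword k = 0; k < 4; ++k) {
          const float v = in(2 * i + k % 2, 2 * j + k / 2, c);
          if (v > best) { best = v; bk = k; }
        }
        out(i, j, c) = best;
        argmax(i, j, c) = bk;
      }
  return out;
}

fcube pool_backward(const fcube& dOut, const ucube& argmax, uword H, uword W) {
  const uword H2 = dOut.n_rows, W2 = dOut.n_cols, C = dOut.n_slices;
  fcube dIn(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W2; ++j)
      for (uword i = 0; i < H2; ++i) {
        const uword k = argmax(i, j, c);
        dIn(2 * i + k % 2, 2 * j + k / 2, c) += dOut(i, j, c);
      }
  return dIn;
}

// ---- 2x2 stride-2 transposed conv ------------------------------------------

fcube up_forward(const fcube& in, const Conv& L) {
  const uword h = in.n_rows, w = in.n_cols, Cout = L.W.n_cols;
  fcube out(2 * h, 2 * w, Cout);
  fmat inm(const_cast<float*>(in.memptr()), h * w, in.n_slices, false, true);
  for (int k = 0; k < 4; ++k) {
    const uword dy = k / 2, dx = k % 2;
    fmat o = inm * L.W.slice(k);
    o.each_row() += L.b.t();
    for (uword c = 0; c < Cout; ++c)
      for (uword j = 0; j < w; ++j)
        for (uword i = 0; i < h; ++i)
          out(2 * i + dy, 2 * j + dx, c) = o(j * h + i, c);
  }
  return out;
}

fcube up_backward(const fcube& in, Conv& L, const fcube& dOut) {
  const uword h = in.n_rows, w = in.n_cols, Cin = in.n_slices, Cout = L.W.n_cols;
  fmat inm(const_cast<float*>(in.memptr()), h * w, Cin, false, true);
  fcube dIn(h, w, Cin, fill::zeros);
  fmat dInm(dIn.memptr(), h * w, Cin, false, true);
  fmat g(h * w, Cout);
  for (int k = 0; k < 4; ++k) {
    const uword dy = k / 2, dx = k % 2;
    for (uword c = 0; c < Cout; ++c)
      for (uword j = 0; j < w; ++j)
        for (uword i = 0; i < h; ++i)
          g(j * h + i, c) = dOut(2 * i + dy, 2 * j + dx, c);
    L.gW.slice(k) += inm.t() * g;
    L.gb += sum(g, 0).t();
    dInm += g * L.W.slice(k).t();
  }
  return dIn;
}

inline void relu_inplace(fcube& x) {
  x.transform([](float v) { return v > 0 ? v : 0.0f; });
}

fcube relu_mask(const fcube& act) {
  fcube m = act;
  m.transform([](float v) { return v > 0 ? 1.0f : 0.0f; });
  return m;
}

// ---- network ----------------------------------------------------------------

struct UNet {
  int depth;
  bool with_grad;
  std::vector<Conv> enc;   // 2 per level
  std::vector<Conv> bott;  // 2
  std::vector<Conv> up;    // 1 per level (deepest first)
  std::vector<Conv> dec;   // 2 per level (deepest first)
  Conv fin;

  UNet(List params, int depth_, bool with_grad_)
      : depth(depth_), with_grad(with_grad_) {
    size_t idx = 0;
    auto take = [&](std::vector<Conv>& dst, int n) {
      for (int i = 0; i < n; ++i) {
        Conv L;
        L.W = as_fcube(params[idx++]);
        L.b = as_fvec(params[idx++]);
        if (with_grad) {
          L.gW.zeros(L.W.n_rows, L.W.n_cols, L.W.n_slices);
          L.gb.zeros(L.b.n_elem);
        }
        dst.push_back(std::move(L));
      }
    };
    enc.reserve(2 * depth);
    dec.reserve(2 * depth);
    up.reserve(depth);
    take(enc, 2 * depth);
    take(bott, 2);
    for (int k = 0; k < depth; ++k) {
      take(up, 1);
      take(dec, 2);
    }
    std::vector<Conv> last;
    take(last, 1);
    fin = std::move(last[0]);
  }

  // add accumulated gradients into the R-side double arrays
  void flush_grads(List grads) const {
    size_t idx = 0;
    auto put = [&](const Conv& L) {
      NumericVector gw = grads[idx++];
      for (uword i = 0; i < L.gW.n_elem; ++i) gw[i] += L.gW(i);
      NumericVector gb = grads[idx++];
      for (uword i = 0; i < L.gb.n_elem; ++i) gb[i] += L.gb(i);
    };
    for (const auto& L : enc) put(L);
    for (const auto& L : bott) put(L);
    for (int k = 0; k < depth; ++k) {
      put(up[k]);
      put(dec[2 * k]);
      put(dec[2 * k + 1]);
    }
    put(fin);
  }
};

struct Cache {
  std::vector<fcube> conv_in;    // input of every conv/up layer, execution order
  std::vector<fcube> conv_out;   // post-ReLU conv outputs (ReLU mask source)
  std::vector<fcube> skips;      // encoder skip tensors
  std::vector<ucube> pool_idx;
  fcube last;                    // decoder output feeding the 1x1 conv
};

fmat unet_forward_impl(UNet& net, const fmat& x, Cache* cc) {
  fcube cur(x.n_rows, x.n_cols, 1);
  cur.slice(0) = x;
  std::vector<fcube> skips;
  std::vector<ucube> pidx;
  auto run_conv = [&](const Conv& L, const fcube& in) {
    fcube out = conv3_forward(in, L);
    relu_inplace(out);
    if (cc) { cc->conv_in.push_back(in); cc->conv_out.push_back(out); }
    return out;
  };
  for (int k = 0; k < net.depth; ++k) {
    fcube a1 = run_conv(net.enc[2 * k], cur);
    fcube a2 = run_conv(net.enc[2 * k + 1], a1);
    skips.push_back(a2);
    ucube idx;
    cur = pool_forward(a2, idx);
    pidx.push_back(std::move(idx));
  }
  cur = run_conv(net.bott[0], cur);
  cur = run_conv(net.bott[1], cur);
  for (int k = 0; k < net.depth; ++k) {  // deepest level first
    if (cc) cc->conv_in.push_back(cur);  // up-conv input
    fcube u = up_forward(cur, net.up[k]);
    const fcube& skip = skips[net.depth - 1 - k];
    fcube cat = join_slices(u, skip);
    fcube a1 = run_conv(net.dec[2 * k], cat);
    cur = run_conv(net.dec[2 * k + 1], a1);
  }
  fmat curm(cur.memptr(), cur.n_rows * cur.n_cols, cur.n_slices, false, true);
  fvec lv = curm * vectorise(net.fin.W) + net.fin.b(0);
  fmat logit(cur.n_rows, cur.n_cols);
  std::copy(lv.begin(), lv.end(), logit.begin());
  if (cc) {
    cc->skips = std::move(skips);
    cc->pool_idx = std::move(pidx);
    cc->last = std::move(cur);
  }
  return logit;
}

// stable sigmoid in double precision (outputs are probabilities)
mat sigmoid_d(const fmat& z) {
  mat p(z.n_rows, z.n_cols);
  for (uword i = 0; i < z.n_elem; ++i) {
    const double v = z(i);
    p(i) = v >= 0 ? 1.0 / (1.0 + std::exp(-v)) : std::exp(v) / (1.0 + std::exp(v));
  }
  return p;
}

// mean binary cross-entropy from logits (numerically stable)
double bce_from_logits(const fmat& z, const fmat& y) {
  double s = 0;
  for (uword i = 0; i < z.n_elem; ++i) {
    const double zi = z(i);
    s += std::max(zi, 0.0) - zi * (double)y(i) + std::log1p(std::exp(-std::abs(zi)));
  }
  return s / z.n_elem;
}

// full backward; accumulates parameter gradients inside `net`
void unet_backward_impl(UNet& net, Cache& cc, const fmat& dlogit) {
  const int n = net.depth;
  fmat lastm(cc.last.memptr(), cc.last.n_rows * cc.last.n_cols, cc.last.n_slices,
             false, true);
  fvec dl(const_cast<float*>(dlogit.memptr()), dlogit.n_elem, false, true);
  fvec gw = lastm.t() * dl;
  net.fin.gW.slice(0) += fmat(gw.memptr(), net.fin.gW.n_rows, 1, false, true);
  net.fin.gb(0) += accu(dl);
  fmat dcurm = dl * vectorise(net.fin.W).t();  // (HW x C1)
  fcube dcur(dcurm.memptr(), cc.last.n_rows, cc.last.n_cols, cc.last.n_slices);

  // conv caches are in execution order; up-conv inputs went into conv_in
  // without a matching conv_out entry, so the indices advance differently
  int in_i = (int)cc.conv_in.size() - 1;
  int out_i = (int)cc.conv_out.size() - 1;

  std::vector<fcube> dskips(n);
  for (int k = n - 1; k >= 0; --k) {  // shallowest decoder level first
    for (int c = 1; c >= 0; --c) {
      dcur %= relu_mask(cc.conv_out[out_i]);
      dcur = conv3_backward(cc.conv_in[in_i], net.dec[2 * k + c], dcur);
      --out_i; --in_i;
    }
    const uword ck = dcur.n_slices / 2;  // cat = [up output, skip]
    fcube du = dcur.slices(0, ck - 1);
    dskips[n - 1 - k] = dcur.slices(ck, 2 * ck - 1);
    dcur = up_backward(cc.conv_in[in_i], net.up[k], du);
    --in_i;
  }
  for (int c = 1; c >= 0; --c) {
    dcur %= relu_mask(cc.conv_out[out_i]);
    dcur = conv3_backward(cc.conv_in[in_i], net.bott[c], dcur);
    --out_i; --in_i;
  }
  for (int k = n - 1; k >= 0; --k) {  // deepest encoder level first
    const fcube& skip = cc.skips[k];
    fcube da2 = pool_backward(dcur, cc.pool_idx[k], skip.n_rows, skip.n_cols);
    da2 += dskips[k];
    dcur = std::move(da2);
    for (int c = 1; c >= 0; --c) {
      dcur %= relu_mask(cc.conv_out[out_i]);
      dcur = conv3_backward(cc.conv_in[in_i], net.enc[2 * k + c], dcur);
      --out_i; --in_i;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_unet_forward(List params, NumericMatrix x, int depth) {
  UNet net(params, depth, false);
  fmat xm = as_fmat(x);
  fmat logit = unet_forward_impl(net, xm, nullptr);
  return Rcpp::wrap(sigmoid_d(logit));
}

// loss_type: 0 = binary cross-entropy, 1 = soft Dice, 2 = their sum.
// The soft-Dice term is 1 - (2 sum(p*y) + s) / (sum(p) + sum(y) + s) per
// image with smoothing s = 1.
// [[Rcpp::export]]
double cpp_unet_batch_grad(List params, List grads, List xs, List ys, int depth,
                           int loss_type) {
  UNet net(params, depth, true);
  double total = 0;
  const int n = xs.size();
  const float s = 1.0f;
  for (int i = 0; i < n; ++i) {
    fmat x = as_fmat(xs[i]);
    fmat y = as_fmat(ys[i]);
    Cache cc;
    fmat logit = unet_forward_impl(net, x, &cc);
    fmat p = conv_to<fmat>::from(sigmoid_d(logit));
    fmat dlogit(p.n_rows, p.n_cols, fill::zeros);
    double loss = 0;
    if (loss_type == 0 || loss_type == 2) {
      loss += bce_from_logits(logit, y);
      dlogit += (p - y) / (float)p.n_elem;
    }
    if (loss_type == 1 || loss_type == 2) {
      const float S12 = accu(p) + accu(y) + s;
      const float num = 2.0f * accu(p % y) + s;
      loss += 1.0 - num / S12;
      // d(1 - num/S12)/dp = -(2*y*S12 - num) / S12^2, chained through the
      // sigmoid derivative p(1-p)
      fmat dLdp = -(2.0f * y * S12 - num) / (S12 * S12);
      dlogit += dLdp % p % (1.0f - p);
    }
    dlogit /= (float)n;
    total += loss;
    unet_backward_impl(net, cc, dlogit);
  }
  net.flush_grads(grads);
  return total / n;
}
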