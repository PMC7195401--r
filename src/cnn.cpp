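// Small convolutional network with dropout, used as the patch classifier.
//
// Fixed architecture family: B blocks of [3x3 conv, stride 2, zero pad 1]
// -> ReLU -> (optional) multiplicative dropout mask, then global average
// pooling, a dropout mask on the pooled features, and a dense 2-unit
// softmax head.  Dropout masks are either passed in explicitly or drawn
// inline from R's RNG stream in a documented order, so deterministic
// replay (and an independent pure-R oracle) can reproduce any stochastic
// forward pass bit for bit.
//
// Weight layout contract (shared with the R oracle in the test suite):
//   conv weight b: matrix C_out x (9 * C_in), column index k (0-based)
//     k = c * 9 + dj * 3 + di   for input channel c, kernel offset (di, dj)
//   with output pixel (i, j) reading input pixel (i*2 - 1 + di, j*2 - 1 + dj).
//   dense weight: 2 x C_B, bias length 2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static const int STRIDE = 2;
static const int PAD = 1;
static const int K = 3;

static inline int out_dim(int n) { return (n + 2 * PAD - K) / STRIDE + 1; }

static cube as_cube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("patch must be a 3-d array (H x W x C)");
  return cube(const_cast<double*>(x.begin()), d[0], d[1], d[2], false, true);
}

static mat im2col(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_dim(H), Wo = out_dim(W);
  mat out(9 * C, Ho * Wo, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < K; ++dj)
      for (int di = 0; di < K; ++di) {
        const int rk = c * 9 + dj * 3 + di;
        for (int j = 0; j < Wo; ++j) {
          const int jj = j * STRIDE - PAD + dj;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int ii = i * STRIDE - PAD + di;
            if (ii < 0 || ii >= H) continue;
            out(rk, j * Ho + i) = x(ii, jj, c);
          }
        }
      }
  return out;
}

static cube col2im(const mat& cols, int H, int W, int C) {
  const int Ho = out_dim(H), Wo = out_dim(W);
  cube out(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < K; ++dj)
      for (int di = 0; di < K; ++di) {
        const int rk = c * 9 + dj * 3 + di;
        for (int j = 0; j < Wo; ++j) {
          const int jj = j * STRIDE - PAD + dj;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int ii = i * STRIDE - PAD + di;
            if (ii < 0 || ii >= H) continue;
            out(ii, jj, c) += cols(rk, j * Ho + i);
          }
        }
      }
  return out;
}

struct Params {
  std::vector<mat> Wc;
  std::vector<vec> bc;
  mat Wd;
  vec bd;
};

static Params unpack(const List& params) {
  Params p;
  List Wc = params["Wc"], bc = params["bc"];
  for (int b = 0; b < Wc.size(); ++b) {
    p.Wc.push_back(as<mat>(Wc[b]));
    p.bc.push_back(as<vec>(bc[b]));
  }
  p.Wd = as<mat>(params["Wd"]);
  p.bd = as<vec>(params["bd"]);
  return p;
}

// exact 2x area-mean pooling with ceiling dims (partial edge blocks average
// the pixels present) -- same semantics as the pyramid downsampler
static cube pool2_cube(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  cube out(Ho, Wo, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        out(i / 2, j / 2, c) += x(i, j, c);
  for (int j = 0; j < Wo; ++j) {
    const int cw = std::min(2, W - 2 * j);
    for (int i = 0; i < Ho; ++i) {
      const int ch = std::min(2, H - 2 * i);
      const double k = 1.0 / (cw * ch);
      for (int c = 0; c < C; ++c) out(i, j, c) *= k;
    }
  }
  return out;
}

static vec softmax2(const vec& z) {
  vec s = z - z.max();
  vec e = exp(s);
  return e / accu(e);
}

struct Cache {
  std::vector<mat> cols;     // im2col of each block input
  std::vector<mat> pre;      // pre-ReLU activations, C_out x (Ho*Wo)
  std::vector<mat> mask;     // dropout masks actually applied (may be empty)
  std::vector<int> Hin, Win; // input dims per block
  vec h;                     // pooled features after the head dropout mask
  vec hmask;                 // head dropout mask (empty when none)
  vec probs;
};

// Forward one sample.
//   masks:  R list of arrays (Ho x Wo x C_out) per block, or R_NilValue.
//   p_drop: if >= 0 and masks is NULL, inverted-scale Bernoulli masks are
//           drawn inline from R's RNG, block by block, in the exact order
//           of `(runif(Ho*Wo*C) >= p) / (1 - p)` filled column-major --
//           the same stream an R-side replay would produce.
static Cache forward_one(const Params& p, const cube& x0,
                         const Nullable<List>& masks, double p_drop,
                         bool keep_cache, int stem = 0) {
  const int B = (int)p.Wc.size();
  Cache cc;
  cube x = x0;
  for (int s = 0; s < stem; ++s) x = pool2_cube(x);
  List ml;
  bool has_masks = masks.isNotNull();
  if (has_masks) {
    ml = masks.get();
    if ((int)ml.size() != B + 1)
      stop("masks must have one entry per conv block plus a head mask");
  }
  const bool draw = !has_masks && p_drop >= 0.0;
  for (int b = 0; b < B; ++b) {
    const int H = x.n_rows, W = x.n_cols;
    const int Ho = out_dim(H), Wo = out_dim(W);
    const int Co = p.Wc[b].n_rows;
    mat cols = im2col(x);
    mat a = p.Wc[b] * cols;           // Co x (Ho*Wo)
    a.each_col() += p.bc[b];
    mat r = clamp(a, 0.0, datum::inf);
    mat mk;
    if (has_masks) {
      NumericVector mv = ml[b];
      IntegerVector md = mv.attr("dim");
      if (md.size() != 3 || md[0] != Ho || md[1] != Wo || md[2] != Co)
        stop("dropout mask %d has wrong dimensions", b + 1);
      cube m(mv.begin(), Ho, Wo, Co, false, true);
      mk.set_size(Co, Ho * Wo);
      for (int c = 0; c < Co; ++c)
        mk.row(c) = vectorise(m.slice(c)).t();
      r %= mk;
    } else if (draw) {
      const double keep = 1.0 - p_drop;
      mk.set_size(Co, Ho * Wo);
      // column-major cube order: all of slice (channel) 0 first
      for (int c = 0; c < Co; ++c)
        for (int ij = 0; ij < Ho * Wo; ++ij)
          mk(c, ij) = (unif_rand() >= p_drop) ? 1.0 / keep : 0.0;
      r %= mk;
    }
    if (keep_cache) {
      cc.cols.push_back(cols);
      cc.pre.push_back(a);
      cc.mask.push_back(mk);
      cc.Hin.push_back(H);
      cc.Win.push_back(W);
    }
    // reshape rows back into a cube for the next block
    cube nx(Ho, Wo, Co);
    for (int c = 0; c < Co; ++c)
      nx.slice(c) = reshape(r.row(c), Ho, Wo);
    x = nx;
  }
  vec h(p.Wd.n_cols);
  for (uword c = 0; c < x.n_slices; ++c) h(c) = accu(x.slice(c)) / (x.n_rows * x.n_cols);
  if (has_masks) {
    cc.hmask = as<vec>(ml[B]);
    if (cc.hmask.n_elem != h.n_elem) stop("head mask has wrong length");
    h %= cc.hmask;
  } else if (draw) {
    const double keep = 1.0 - p_drop;
    cc.hmask.set_size(h.n_elem);
    for (uword c = 0; c < h.n_elem; ++c)
      cc.hmask(c) = (unif_rand() >= p_drop) ? 1.0 / keep : 0.0;
    h %= cc.hmask;
  }
  cc.h = h;
  cc.probs = softmax2(p.Wd * h + p.bd);
  return cc;
}

// [[Rcpp::export(name = ".cpp_forward")]]
NumericVector cpp_forward(List params, NumericVector x, Nullable<List> masks,
                          int stem = 0) {
  Params p = unpack(params);
  Cache cc = forward_one(p, as_cube(x), masks, -1.0, false, stem);
  return NumericVector(cc.probs.begin(), cc.probs.end());
}

// Stochastic forward passes with dropout drawn inline from R's RNG stream
// (one mask set per draw, consumed sequentially).  Returns T x 2 matrix.
// [[Rcpp::export(name = ".cpp_forward_mc")]]
NumericMatrix cpp_forward_mc(List params, NumericVector x, double p_drop,
                             int T, int stem = 0) {
  Params p = unpack(params);
  // deep copy: as_cube() binds R memory with fixed size, but stem pooling
  // below reassigns the cube
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 3) stop("patch must be a 3-d array (H x W x C)");
  cube xc(x.begin(), xd[0], xd[1], xd[2]); // copying constructor
  for (int s = 0; s < stem; ++s) xc = pool2_cube(xc);
  NumericMatrix out(T, 2);
  for (int t = 0; t < T; ++t) {
    Cache cc = forward_one(p, xc, R_NilValue, p_drop, false);
    out(t, 0) = cc.probs(0);
    out(t, 1) = cc.probs(1);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_forward_batch")]]
NumericMatrix cpp_forward_batch(List params, List xs, Nullable<List> mask_list,
                                int stem = 0) {
  Params p = unpack(params);
  const int n = xs.size();
  NumericMatrix out(n, 2);
  List ml;
  bool has = mask_list.isNotNull();
  if (has) ml = mask_list.get();
  for (int i = 0; i < n; ++i) {
    Nullable<List> mi = R_NilValue;
    if (has) mi = Nullable<List>(ml[i]);
    Cache cc = forward_one(p, as_cube(xs[i]), mi, -1.0, false, stem);
    out(i, 0) = cc.probs(0);
    out(i, 1) = cc.probs(1);
  }
  return out;
}

// One Adam step on a mini-batch (mean cross-entropy gradient).  y is a
// 0-based class index.  Dropout masks are drawn inline from R's RNG
// (sample by sample) when p_drop >= 0.  `state` carries the first/second
// moment estimates (same shapes as params) and the step counter is
// `step_t` (1-based).  Returns updated params/state and the pre-update
// mean loss.
// [[Rcpp::export(name = ".cpp_train_batch")]]
List cpp_train_batch(List params, List xs, IntegerVector y, double p_drop,
                     double lr, List state, int step_t, int stem = 0) {
  const double B1 = 0.9, B2 = 0.999, EPS = 1e-8;
  Params p = unpack(params);
  Params m1 = unpack(state["m"]);
  Params m2 = unpack(state["v"]);
  const int B = (int)p.Wc.size();
  const int n = xs.size();
  if (y.size() != n) stop("labels do not match batch size");

  Params g;
  for (int b = 0; b < B; ++b) {
    g.Wc.push_back(mat(size(p.Wc[b]), fill::zeros));
    g.bc.push_back(vec(size(p.bc[b]), fill::zeros));
  }
  g.Wd = mat(size(p.Wd), fill::zeros);
  g.bd = vec(size(p.bd), fill::zeros);

  double loss = 0.0;
  for (int s = 0; s < n; ++s) {
    cube x = as_cube(xs[s]);
    Cache cc = forward_one(p, x, R_NilValue, p_drop, true, stem);
    const int cls = y[s];
    if (cls < 0 || cls > 1) stop("class index out of range");
    loss += -std::log(std::max(cc.probs(cls), 1e-12));

    vec dz = cc.probs;
    dz(cls) -= 1.0;
    g.Wd += dz * cc.h.t();
    g.bd += dz;
    vec dh = p.Wd.t() * dz;
    if (cc.hmask.n_elem > 0) dh %= cc.hmask;

    // walk blocks backwards
    mat dpost; // gradient w.r.t. post-activation of current block, Co x (Ho*Wo)
    for (int b = B - 1; b >= 0; --b) {
      const int Ho = out_dim(cc.Hin[b]), Wo = out_dim(cc.Win[b]);
      const int Co = p.Wc[b].n_rows;
      mat d(Co, Ho * Wo);
      if (b == B - 1) {
        for (int c = 0; c < Co; ++c)
          d.row(c).fill(dh(c) / (Ho * Wo));
      } else {
        d = dpost;
      }
      // undo dropout mask
      if (cc.mask[b].n_elem > 0) d %= cc.mask[b];
      // ReLU gate
      d %= conv_to<mat>::from(cc.pre[b] > 0.0);
      g.Wc[b] += d * cc.cols[b].t();
      g.bc[b] += sum(d, 1);
      if (b > 0) {
        mat dcols = p.Wc[b].t() * d;
        const int Hp = cc.Hin[b], Wp = cc.Win[b];
        const int Cp = p.Wc[b - 1].n_rows;
        cube dx = col2im(dcols, Hp, Wp, Cp);
        // convert to the post-activation row layout of block b-1
        dpost.set_size(Cp, Hp * Wp);
        for (int c = 0; c < Cp; ++c)
          dpost.row(c) = vectorise(dx.slice(c)).t();
      }
    }
  }
  loss /= n;

  const double sc = 1.0 / n;
  const double corr1 = 1.0 - std::pow(B1, step_t);
  const double corr2 = 1.0 - std::pow(B2, step_t);
  auto adam = [&](mat& par, mat& mm, mat& vv, const mat& grad) {
    mat gbar = sc * grad;
    mm = B1 * mm + (1.0 - B1) * gbar;
    vv = B2 * vv + (1.0 - B2) * square(gbar);
    par -= lr * (mm / corr1) / (sqrt(vv / corr2) + EPS);
  };
  auto adam_v = [&](vec& par, vec& mm, vec& vv, const vec& grad) {
    vec gbar = sc * grad;
    mm = B1 * mm + (1.0 - B1) * gbar;
    vv = B2 * vv + (1.0 - B2) * square(gbar);
    par -= lr * (mm / corr1) / (sqrt(vv / corr2) + EPS);
  };
  for (int b = 0; b < B; ++b) {
    adam(p.Wc[b], m1.Wc[b], m2.Wc[b], g.Wc[b]);
    adam_v(p.bc[b], m1.bc[b], m2.bc[b], g.bc[b]);
  }
  adam(p.Wd, m1.Wd, m2.Wd, g.Wd);
  adam_v(p.bd, m1.bd, m2.bd, g.bd);

  auto pack = [&](const Params& q) {
    List Wc(B), bc(B);
    for (int b = 0; b < B; ++b) { Wc[b] = wrap(q.Wc[b]); bc[b] = wrap(q.bc[b]); }
    return List::create(_["Wc"] = Wc, _["bc"] = bc,
                        _["Wd"] = wrap(q.Wd), _["bd"] = wrap(q.bd));
  };
  return List::create(
    _["params"] = pack(p),
    _["state"] = List::create(_["m"] = pack(m1), _["v"] = pack(m2)),
    _["loss"] = loss);
}
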