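// Core numerical kernels: 8-connectivity component labeling for the
// segmenter, and a small CPU convolutional-network engine (im2col GEMM
// convolutions, 2x2 max pooling, inverted dropout, Adam) used by the
// closed-set classifier and the open-set heads.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// 8-connectivity connected-component labeling (union-find, two-pass).
// mask: integer matrix (H x W), nonzero = foreground. Returns labels 1..n.
// ---------------------------------------------------------------------------

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
  return i;
}
static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export(name = ".label_components8")]]
IntegerMatrix label_components8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  int next = 1;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if (mask(y, x) == 0) continue;
      // previously visited 8-neighbours: (x-1,y-1),(x-1,y),(x-1,y+1),(x,y-1)
      int nb[4] = {0, 0, 0, 0};
      if (x > 0) {
        if (y > 0)     nb[0] = lab(y - 1, x - 1);
        nb[1] = lab(y, x - 1);
        if (y < H - 1) nb[2] = lab(y + 1, x - 1);
      }
      if (y > 0) nb[3] = lab(y - 1, x);
      int m = 0;
      for (int k = 0; k < 4; ++k) if (nb[k] > 0 && (m == 0 || nb[k] < m)) m = nb[k];
      if (m == 0) {
        lab(y, x) = next;
        parent.push_back(next);
        ++next;
      } else {
        lab(y, x) = m;
        for (int k = 0; k < 4; ++k) if (nb[k] > 0) uf_union(parent, m, nb[k]);
      }
    }
  }
  // relabel to consecutive ids
  std::vector<int> remap(next, 0);
  int nlab = 0;
  for (int i = 1; i < next; ++i) {
    int r = uf_find(parent, i);
    if (remap[r] == 0) remap[r] = ++nlab;
  }
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      if (lab(y, x) > 0) lab(y, x) = remap[uf_find(parent, lab(y, x))];
  return lab;
}

// ---------------------------------------------------------------------------
// Separable binary dilation with a square structuring element of Chebyshev
// radius r (a horizontal then vertical 1D max filter).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".binary_dilate_cpp")]]
LogicalMatrix binary_dilate_cpp(LogicalMatrix m, int r) {
  const int H = m.nrow(), W = m.ncol();
  LogicalMatrix tmp(H, W), out(H, W);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      bool v = false;
      const int lo = std::max(0, x - r), hi = std::min(W - 1, x + r);
      for (int xx = lo; xx <= hi && !v; ++xx) v = m(y, xx);
      tmp(y, x) = v;
    }
  }
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      bool v = false;
      const int lo = std::max(0, y - r), hi = std::min(H - 1, y + r);
      for (int yy = lo; yy <= hi && !v; ++yy) v = tmp(yy, x);
      out(y, x) = v;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Micro-CNN engine.
//
// Architecture: nb conv blocks (3x3, pad 1, ReLU, 2x2 maxpool; blocks >= 2
// followed by dropout), then dense(hidden, ReLU), dense(K). Spatial index
// within a map is p = x*H + y (column-major, matching R matrices).
// Activations for a batch of B images are (C) x (B*HW) matrices with the
// column of image i, pixel p at i*HW + p.
// ---------------------------------------------------------------------------

struct NetShape {
  int S;                    // input side
  std::vector<int> ch;      // channels: ch[0]=1 input, then widths
  int hidden, K, nb, flat;
  std::vector<int> side;    // spatial side before each block
};

static NetShape shape_from_params(const List& params) {
  NetShape ns;
  ns.S = as<int>(params["input_size"]);
  IntegerVector w = params["widths"];
  ns.nb = w.size();
  ns.ch.resize(ns.nb + 1);
  ns.ch[0] = 1;
  for (int i = 0; i < ns.nb; ++i) ns.ch[i + 1] = w[i];
  ns.hidden = as<int>(params["hidden"]);
  ns.K = as<int>(params["n_out"]);
  ns.side.resize(ns.nb + 1);
  ns.side[0] = ns.S;
  for (int i = 1; i <= ns.nb; ++i) {
    if (ns.side[i - 1] % 2 != 0) stop("input size must be divisible by 2^n_blocks");
    ns.side[i] = ns.side[i - 1] / 2;
  }
  ns.flat = ns.ch[ns.nb] * ns.side[ns.nb] * ns.side[ns.nb];
  return ns;
}

// im2col for 3x3 pad-1 kernels: in (C x B*HW) -> out (9C x B*HW)
static void im2col3(const arma::mat& in, arma::mat& out, int H, int B) {
  const int C = in.n_rows, HW = H * H;
  out.set_size(9 * C, (arma::uword)B * HW);
  out.zeros();
  for (int b = 0; b < B; ++b) {
    const arma::uword off = (arma::uword)b * HW;
    for (int x = 0; x < H; ++x) {
      for (int y = 0; y < H; ++y) {
        const arma::uword pc = off + (arma::uword)x * H + y;
        int k = 0;
        for (int dx = -1; dx <= 1; ++dx) {
          for (int dy = -1; dy <= 1; ++dy, ++k) {
            const int xx = x + dx, yy = y + dy;
            if (xx < 0 || xx >= H || yy < 0 || yy >= H) continue;
            const arma::uword ps = off + (arma::uword)xx * H + yy;
            for (int c = 0; c < C; ++c) out(9 * c + k, pc) = in(c, ps);
          }
        }
      }
    }
  }
}

// accumulate col-gradient back to image maps: dcol (9C x B*HW) -> din (C x B*HW)
static void col2im3(const arma::mat& dcol, arma::mat& din, int H, int B) {
  const int C = dcol.n_rows / 9, HW = H * H;
  din.zeros(C, (arma::uword)B * HW);
  for (int b = 0; b < B; ++b) {
    const arma::uword off = (arma::uword)b * HW;
    for (int x = 0; x < H; ++x) {
      for (int y = 0; y < H; ++y) {
        const arma::uword pc = off + (arma::uword)x * H + y;
        int k = 0;
        for (int dx = -1; dx <= 1; ++dx) {
          for (int dy = -1; dy <= 1; ++dy, ++k) {
            const int xx = x + dx, yy = y + dy;
            if (xx < 0 || xx >= H || yy < 0 || yy >= H) continue;
            const arma::uword ps = off + (arma::uword)xx * H + yy;
            for (int c = 0; c < C; ++c) din(c, ps) += dcol(9 * c + k, pc);
          }
        }
      }
    }
  }
}

// 2x2 maxpool: in (C x B*HW) -> out (C x B*hw/4); argmax index recorded
static void maxpool2(const arma::mat& in, arma::mat& out, arma::umat& amax,
                     int H, int B) {
  const int C = in.n_rows, h = H / 2, HW = H * H, hw = h * h;
  out.set_size(C, (arma::uword)B * hw);
  amax.set_size(C, (arma::uword)B * hw);
  for (int b = 0; b < B; ++b) {
    const arma::uword offi = (arma::uword)b * HW, offo = (arma::uword)b * hw;
    for (int x = 0; x < h; ++x) {
      for (int y = 0; y < h; ++y) {
        const arma::uword po = offo + (arma::uword)x * h + y;
        const arma::uword p00 = offi + (arma::uword)(2 * x) * H + 2 * y;
        const arma::uword idx[4] = {p00, p00 + 1, p00 + (arma::uword)H,
                                    p00 + (arma::uword)H + 1};
        for (int c = 0; c < C; ++c) {
          double best = in(c, idx[0]);
          arma::uword bi = idx[0];
          for (int k = 1; k < 4; ++k)
            if (in(c, idx[k]) > best) { best = in(c, idx[k]); bi = idx[k]; }
          out(c, po) = best;
          amax(c, po) = bi;
        }
      }
    }
  }
}

static void unpool2(const arma::mat& dout, const arma::umat& amax,
                    arma::mat& din, int H, int B) {
  const int C = dout.n_rows, HW = H * H;
  din.zeros(C, (arma::uword)B * HW);
  for (arma::uword j = 0; j < dout.n_cols; ++j)
    for (int c = 0; c < C; ++c) din(c, amax(c, j)) += dout(c, j);
}

struct ForwardCache {
  std::vector<arma::mat> col;    // im2col inputs per block
  std::vector<arma::mat> conv;   // post-ReLU conv outputs
  std::vector<arma::mat> pool;   // post-pool (and post-dropout) outputs
  std::vector<arma::umat> amax;
  std::vector<arma::mat> dropmask;
  arma::mat flat, hid, out;
};

static arma::mat getm(const List& p, const char* nm) {
  return as<arma::mat>(p[nm]);
}

static void net_forward(const List& params, const NetShape& ns,
                        const arma::mat& X, bool train, double dropout,
                        std::mt19937_64* rng, ForwardCache& fc) {
  const int B = X.n_cols / 1;
  // X: (S*S) x B  -> maps (1 x B*HW)
  const int HW = ns.S * ns.S;
  arma::mat maps(1, (arma::uword)B * HW);
  for (int b = 0; b < B; ++b)
    maps.cols((arma::uword)b * HW, (arma::uword)(b + 1) * HW - 1) =
      X.col(b).t();
  fc.col.resize(ns.nb); fc.conv.resize(ns.nb); fc.pool.resize(ns.nb);
  fc.amax.resize(ns.nb); fc.dropmask.assign(ns.nb, arma::mat());
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  for (int l = 0; l < ns.nb; ++l) {
    const int H = ns.side[l];
    char wn[8], bn[8];
    snprintf(wn, 8, "W%d", l + 1); snprintf(bn, 8, "b%d", l + 1);
    arma::mat W = getm(params, wn);
    arma::vec bb = as<arma::vec>(params[bn]);
    im2col3(maps, fc.col[l], H, B);
    arma::mat Z = W * fc.col[l];
    Z.each_col() += bb;
    Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
    fc.conv[l] = Z;
    maxpool2(Z, fc.pool[l], fc.amax[l], H, B);
    if (l >= 1 && dropout > 0.0 && train) {
      arma::mat m(fc.pool[l].n_rows, fc.pool[l].n_cols);
      for (arma::uword i = 0; i < m.n_elem; ++i)
        m(i) = (unif(*rng) >= dropout) ? 1.0 / (1.0 - dropout) : 0.0;
      fc.dropmask[l] = m;
      fc.pool[l] %= m;
    }
    maps = fc.pool[l];
  }
  // flatten: (C x B*hw) -> (C*hw) x B
  const int hw = ns.side[ns.nb] * ns.side[ns.nb], C = ns.ch[ns.nb];
  fc.flat.set_size((arma::uword)C * hw, B);
  for (int b = 0; b < B; ++b)
    fc.flat.col(b) = arma::vectorise(
      maps.cols((arma::uword)b * hw, (arma::uword)(b + 1) * hw - 1));
  arma::mat W6 = getm(params, "Wd1"), W7 = getm(params, "Wd2");
  arma::vec b6 = as<arma::vec>(params["bd1"]), b7 = as<arma::vec>(params["bd2"]);
  fc.hid = W6 * fc.flat;
  fc.hid.each_col() += b6;
  fc.hid.transform([](double v) { return v > 0.0 ? v : 0.0; });
  fc.out = W7 * fc.hid;
  fc.out.each_col() += b7;
}

static arma::mat softmax_cols(const arma::mat& Z) {
  arma::mat P = Z;
  for (arma::uword j = 0; j < P.n_cols; ++j) {
    arma::vec c = P.col(j);
    c -= c.max();
    c = arma::exp(c);
    P.col(j) = c / arma::accu(c);
  }
  return P;
}

// loss gradient on fc.out; returns mean loss
static double loss_grad(const arma::mat& out, const arma::ivec& y,
                        const std::string& loss, const arma::vec& clw,
                        double anchor_mag, double cac_lambda,
                        arma::mat& dout) {
  const int K = out.n_rows, B = out.n_cols;
  dout.set_size(K, B);
  double L = 0.0;
  if (loss == "cac") {
    // anchors a_k = anchor_mag * e_k; d_k = ||f - a_k||
    for (int j = 0; j < B; ++j) {
      arma::vec f = out.col(j);
      arma::vec d(K);
      for (int k = 0; k < K; ++k) {
        arma::vec diff = f;
        diff(k) -= anchor_mag;
        d(k) = std::sqrt(arma::dot(diff, diff)) + 1e-12;
      }
      arma::vec z = -d;
      z -= z.max();
      arma::vec p = arma::exp(z);
      p /= arma::accu(p);
      const int yy = y(j);
      L += -std::log(std::max(p(yy), 1e-12)) + cac_lambda * d(yy);
      arma::vec dLdd = -p;           // from CE on -d: dL/dd_k = y_k - p_k
      dLdd(yy) += 1.0;
      dLdd(yy) += cac_lambda;
      arma::vec g(K, arma::fill::zeros);
      for (int k = 0; k < K; ++k) {
        arma::vec diff = f;
        diff(k) -= anchor_mag;
        g += dLdd(k) * diff / d(k);
      }
      dout.col(j) = g / B;
    }
  } else {
    arma::mat P = softmax_cols(out);
    for (int j = 0; j < B; ++j) {
      const int yy = y(j);
      const double w = clw(yy);
      L += -w * std::log(std::max(P(yy, j), 1e-12));
      arma::vec g = P.col(j) * w;
      g(yy) -= w;
      dout.col(j) = g / B;
    }
  }
  return L / B;
}

struct AdamState {
  std::vector<arma::mat> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
};

// [[Rcpp::export(name = ".cnn_init")]]
List cnn_init(int seed, int input_size, IntegerVector widths, int hidden,
              int n_out) {
  std::mt19937_64 rng((unsigned long long)seed);
  std::normal_distribution<double> norm(0.0, 1.0);
  List params;
  params["input_size"] = input_size;
  params["widths"] = widths;
  params["hidden"] = hidden;
  params["n_out"] = n_out;
  int cin = 1;
  for (int l = 0; l < widths.size(); ++l) {
    const int cout = widths[l];
    arma::mat W(cout, 9 * cin);
    const double sd = std::sqrt(2.0 / (9.0 * cin));
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = sd * norm(rng);
    char wn[8], bn[8];
    snprintf(wn, 8, "W%d", l + 1); snprintf(bn, 8, "b%d", l + 1);
    params[wn] = W;
    params[bn] = arma::vec(cout, arma::fill::zeros);
    cin = cout;
  }
  NetShape ns = shape_from_params(params);
  arma::mat W6(hidden, ns.flat), W7(n_out, hidden);
  const double sd6 = std::sqrt(2.0 / ns.flat), sd7 = std::sqrt(2.0 / hidden);
  for (arma::uword i = 0; i < W6.n_elem; ++i) W6(i) = sd6 * norm(rng);
  for (arma::uword i = 0; i < W7.n_elem; ++i) W7(i) = sd7 * norm(rng);
  params["Wd1"] = W6;
  params["bd1"] = arma::vec(hidden, arma::fill::zeros);
  params["Wd2"] = W7;
  params["bd2"] = arma::vec(n_out, arma::fill::zeros);
  return params;
}

// [[Rcpp::export(name = ".cnn_train")]]
List cnn_train(List params, NumericMatrix Xr, IntegerVector yr,
               NumericMatrix Xvr, IntegerVector yvr, List cfg) {
  NetShape ns = shape_from_params(params);
  arma::mat X(Xr.begin(), Xr.nrow(), Xr.ncol(), true);
  arma::ivec y(yr.size());
  for (int i = 0; i < yr.size(); ++i) y(i) = yr[i];
  arma::mat Xv(Xvr.begin(), Xvr.nrow(), Xvr.ncol(), true);
  arma::ivec yv(yvr.size());
  for (int i = 0; i < yvr.size(); ++i) yv(i) = yvr[i];

  const int epochs = as<int>(cfg["epochs"]);
  const int batch = as<int>(cfg["batch_size"]);
  const double lr = as<double>(cfg["learning_rate"]);
  const double dropout = as<double>(cfg["dropout_rate"]);
  const std::string loss = as<std::string>(cfg["loss"]);
  const double anchor_mag = as<double>(cfg["anchor_magnitude"]);
  const double cac_lambda = as<double>(cfg["cac_lambda"]);
  const int seed = as<int>(cfg["seed"]);
  arma::vec clw = as<arma::vec>(cfg["class_weights"]);
  std::mt19937_64 rng((unsigned long long)seed + 1234567ULL);

  // parameter order for Adam
  std::vector<std::string> pn;
  for (int l = 1; l <= ns.nb; ++l) {
    pn.push_back("W" + std::to_string(l));
    pn.push_back("b" + std::to_string(l));
  }
  pn.push_back("Wd1"); pn.push_back("bd1");
  pn.push_back("Wd2"); pn.push_back("bd2");
  AdamState ad;
  ad.m.resize(pn.size()); ad.v.resize(pn.size());
  for (size_t i = 0; i < pn.size(); ++i) {
    arma::mat P = as<arma::mat>(params[pn[i]]);
    ad.m[i].zeros(P.n_rows, P.n_cols);
    ad.v[i].zeros(P.n_rows, P.n_cols);
  }

  const int N = X.n_cols;
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  NumericVector tr_loss(epochs), val_acc(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double epl = 0.0;
    int nb_batches = 0;
    for (int s = 0; s < N; s += batch) {
      const int e = std::min(s + batch, N);
      const int B = e - s;
      arma::mat Xb(X.n_rows, B);
      arma::ivec yb(B);
      for (int j = 0; j < B; ++j) { Xb.col(j) = X.col(idx[s + j]); yb(j) = y(idx[s + j]); }
      ForwardCache fc;
      net_forward(params, ns, Xb, true, dropout, &rng, fc);
      arma::mat dout;
      epl += loss_grad(fc.out, yb, loss, clw, anchor_mag, cac_lambda, dout);
      ++nb_batches;
      // ---- backward ----
      std::vector<arma::mat> grads(pn.size());
      arma::mat W7 = getm(params, "Wd2"), W6 = getm(params, "Wd1");
      arma::mat dW7 = dout * fc.hid.t();
      arma::vec db7 = arma::sum(dout, 1);
      arma::mat dhid = W7.t() * dout;
      dhid %= arma::conv_to<arma::mat>::from(fc.hid > 0);
      arma::mat dW6 = dhid * fc.flat.t();
      arma::vec db6 = arma::sum(dhid, 1);
      arma::mat dflat = W6.t() * dhid;
      // unflatten to maps (C x B*hw)
      const int hw = ns.side[ns.nb] * ns.side[ns.nb], C = ns.ch[ns.nb];
      arma::mat dmaps(C, (arma::uword)B * hw);
      for (int b = 0; b < B; ++b) {
        arma::mat mcol = arma::reshape(dflat.col(b), C, hw);
        dmaps.cols((arma::uword)b * hw, (arma::uword)(b + 1) * hw - 1) = mcol;
      }
      for (int l = ns.nb - 1; l >= 0; --l) {
        if (l >= 1 && dropout > 0.0) dmaps %= fc.dropmask[l];
        const int H = ns.side[l];
        arma::mat dconv;
        unpool2(dmaps, fc.amax[l], dconv, H, B);
        dconv %= arma::conv_to<arma::mat>::from(fc.conv[l] > 0);
        arma::mat Wl = getm(params, ("W" + std::to_string(l + 1)).c_str());
        grads[2 * l] = dconv * fc.col[l].t();
        grads[2 * l + 1] = arma::sum(dconv, 1);
        if (l > 0) {
          arma::mat dcol = Wl.t() * dconv;
          col2im3(dcol, dmaps, H, B);
        }
      }
      grads[2 * ns.nb] = dW6;
      grads[2 * ns.nb + 1] = db6;
      grads[2 * ns.nb + 2] = dW7;
      grads[2 * ns.nb + 3] = db7;
      // ---- Adam ----
      ++ad.t;
      const double bc1 = 1.0 - std::pow(ad.b1, (double)ad.t);
      const double bc2 = 1.0 - std::pow(ad.b2, (double)ad.t);
      for (size_t i = 0; i < pn.size(); ++i) {
        arma::mat P = as<arma::mat>(params[pn[i]]);
        arma::mat G = grads[i];
        if (G.n_cols != P.n_cols) G = arma::reshape(G, P.n_rows, P.n_cols);
        ad.m[i] = ad.b1 * ad.m[i] + (1 - ad.b1) * G;
        ad.v[i] = ad.b2 * ad.v[i] + (1 - ad.b2) * (G % G);
        P -= lr * (ad.m[i] / bc1) / (arma::sqrt(ad.v[i] / bc2) + ad.eps);
        params[pn[i]] = P;
      }
    }
    tr_loss[ep] = epl / std::max(nb_batches, 1);
    // validation accuracy (eval mode)
    if (Xv.n_cols > 0) {
      ForwardCache fcv;
      net_forward(params, ns, Xv, false, 0.0, nullptr, fcv);
      int ok = 0;
      for (arma::uword j = 0; j < Xv.n_cols; ++j) {
        arma::uword am;
        if (loss == "cac") {
          arma::vec f = fcv.out.col(j), d(ns.K);
          for (int k = 0; k < ns.K; ++k) {
            arma::vec diff = f; diff(k) -= anchor_mag;
            d(k) = arma::norm(diff);
          }
          am = d.index_min();
        } else {
          am = fcv.out.col(j).index_max();
        }
        if ((int)am == yv(j)) ++ok;
      }
      val_acc[ep] = (double)ok / Xv.n_cols;
    } else val_acc[ep] = NA_REAL;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = params, _["train_loss"] = tr_loss,
                      _["val_accuracy"] = val_acc);
}

// [[Rcpp::export(name = ".cnn_forward")]]
NumericMatrix cnn_forward(List params, NumericMatrix Xr, List cfg) {
  NetShape ns = shape_from_params(params);
  arma::mat X(Xr.begin(), Xr.nrow(), Xr.ncol(), false);
  const bool drop_active = as<bool>(cfg["dropout_active"]);
  const double dropout = drop_active ? as<double>(cfg["dropout_rate"]) : 0.0;
  const std::string output = as<std::string>(cfg["output"]);
  std::mt19937_64 rng((unsigned long long)as<int>(cfg["seed"]));
  ForwardCache fc;
  net_forward(params, ns, X, drop_active, dropout, &rng, fc);
  arma::mat out = fc.out;
  if (output == "prob") out = softmax_cols(out);
  return wrap(out);  // K x N
}
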