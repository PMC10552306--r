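// Forward/backward passes, focal loss, Adam, masked sparse layers and RigL
// for the shared-gene-module architectures. Inputs arrive as an (n*G) x C
// matrix whose row r corresponds to (sample s, gene g) with r = s + n*(g-1)
// (column-major flattening of the n x G x C count array), so the shared gene
// module is a single GEMM over all (sample, gene) pairs.
//
// The core computes in single precision (the standard working precision for
// neural-network training); parameters cross the R boundary as doubles.
// Loss accumulation stays in double.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
typedef arma::fmat fm;
typedef arma::fvec fv;

// head kinds
static const int HEAD_LOGREG = 0;
static const int HEAD_HIDDEN = 1;  // biosparse / multiconnect / dense / linear
static const int HEAD_STACKED = 2; // gene-gene sparse layer, then gene-pathway

static inline fm to_f(const arma::mat& x) { return arma::conv_to<fm>::from(x); }
static inline fv to_fv(const arma::vec& x) { return arma::conv_to<fv>::from(x); }
static inline arma::mat to_d(const fm& x) {
  return arma::conv_to<arma::mat>::from(x);
}

// tanh via a cubic-Hermite table on [0, 12] (step 1/64): max abs error
// < 1e-9 (well below fp32 resolution), several times faster than libm and
// fully deterministic.
namespace {
struct TanhTable {
  static const int N = 12 * 64;
  float v[N + 2], d[N + 2];
  TanhTable() {
    for (int i = 0; i <= N + 1; ++i) {
      double x = i / 64.0;
      double t = std::tanh(x);
      v[i] = (float)t;
      d[i] = (float)((1.0 - t * t) / 64.0); // derivative scaled by step
    }
  }
};
static const TanhTable tanh_tab;
}
static inline float fast_tanh(float x) {
  float u = std::fabs(x);
  if (u >= 12.0f) return x > 0 ? 1.0f : -1.0f;
  float s = u * 64.0f;
  int k = (int)s;
  float t = s - k;
  float t2 = t * t, t3 = t2 * t;
  float r = (2 * t3 - 3 * t2 + 1) * tanh_tab.v[k]
          + (t3 - 2 * t2 + t) * tanh_tab.d[k]
          + (-2 * t3 + 3 * t2) * tanh_tab.v[k + 1]
          + (t3 - t2) * tanh_tab.d[k + 1];
  return x < 0 ? -r : r;
}

static inline void add_col_bias(fm& A, const fv& b) {
  for (arma::uword j = 0; j < A.n_cols; ++j) A.col(j) += b(j);
}
static inline void tanh_inplace(fm& A) {
  float* p = A.memptr();
  const arma::uword m = A.n_elem;
  for (arma::uword i = 0; i < m; ++i) p[i] = fast_tanh(p[i]);
}
static inline void act_fwd_inplace(fm& A, int is_tanh) {
  if (is_tanh) tanh_inplace(A);
}
// dZ *= act'(Z), with act' expressed via the activated value (tanh' = 1-a^2)
static inline void act_bwd_inplace(fm& dZ, const fm& A, int is_tanh) {
  if (!is_tanh) return;
  float* d = dZ.memptr();
  const float* a = A.memptr();
  const arma::uword m = dZ.n_elem;
  for (arma::uword i = 0; i < m; ++i) d[i] *= (1.0f - a[i] * a[i]);
}

struct AdamState {
  fm m, v;
  AdamState() {}
  AdamState(arma::uword r, arma::uword c) : m(r, c, arma::fill::zeros),
                                            v(r, c, arma::fill::zeros) {}
};

static inline void adam_step(fm& p, const fm& g, AdamState& st,
                             float lr, float b1, float b2, float eps,
                             float bc1, float bc2) {
  st.m = b1 * st.m + (1.0f - b1) * g;
  st.v = b2 * st.v + (1.0f - b2) * arma::square(g);
  p -= lr * (st.m / bc1) / (arma::sqrt(st.v / bc2) + eps);
}

// focal loss and its gradient wrt the pre-sigmoid score.
// per-sample: y=1 -> -alpha * (1-p)^gamma * log(p)
//             y=0 -> -(1-alpha) * p^gamma * log(1-p)
static double focal_loss_and_grad(const fv& p, const fv& y,
                                  double alpha, double gamma, double clamp,
                                  fv& dscore) {
  const arma::uword B = p.n_elem;
  double loss = 0.0;
  for (arma::uword i = 0; i < B; ++i) {
    double pi = std::min(std::max((double)p(i), clamp), 1.0 - clamp);
    double g;
    if (y(i) > 0.5f) {
      double om = 1.0 - pi;
      loss += -alpha * std::pow(om, gamma) * std::log(pi);
      // d/ds with s the logit (dp/ds = p(1-p))
      g = alpha * (gamma * pi * std::pow(om, gamma) * std::log(pi)
                   - std::pow(om, gamma + 1.0));
    } else {
      double w = 1.0 - alpha;
      loss += -w * std::pow(pi, gamma) * std::log(1.0 - pi);
      g = w * (std::pow(pi, gamma + 1.0)
               - gamma * std::pow(pi, gamma) * (1.0 - pi)
                 * std::log(1.0 - pi));
    }
    dscore(i) = (float)(g / B);
  }
  return loss / (double)B;
}

// [[Rcpp::export]]
double focal_loss_cpp(const arma::vec& p, const arma::vec& y,
                      double alpha, double gamma, double clamp) {
  fv pf = to_fv(p), yf = to_fv(y);
  fv d(p.n_elem, arma::fill::zeros);
  return focal_loss_and_grad(pf, yf, alpha, gamma, clamp, d);
}

struct Net {
  int head_kind, act_gene, act_gene_out, act_hidden;
  int n, G, C, H1, P;
  fm W1;  fv b1;    // gene module hidden
  fv w2;  float b2; // gene module output
  // logreg head
  fv v;   float c_out;
  // hidden head
  fm U;   fv bh;  fv w;  fm M;
  // stacked gene-gene layer
  fm Ugg; fv bgg; fm Mgg;
};

static Net unpack(const List& params, const List& arch, int n, int G, int C) {
  Net net;
  net.n = n; net.G = G; net.C = C;
  net.head_kind = as<int>(arch["head_kind"]);
  net.act_gene = as<int>(arch["act_gene"]);
  net.act_gene_out = arch.containsElementNamed("act_gene_out")
    ? as<int>(arch["act_gene_out"]) : 0;
  net.act_hidden = as<int>(arch["act_hidden"]);
  net.W1 = to_f(as<arma::mat>(params["W1"]));
  net.b1 = to_fv(as<arma::vec>(params["b1"]));
  net.w2 = to_fv(as<arma::vec>(params["w2"]));
  net.b2 = (float)as<double>(params["b2"]);
  net.H1 = net.W1.n_cols;
  net.P = 0;
  if (net.head_kind == HEAD_LOGREG) {
    net.v = to_fv(as<arma::vec>(params["v"]));
    net.c_out = (float)as<double>(params["c"]);
  } else {
    net.U = to_f(as<arma::mat>(params["U"]));
    net.bh = to_fv(as<arma::vec>(params["bh"]));
    net.w = to_fv(as<arma::vec>(params["w"]));
    net.c_out = (float)as<double>(params["c"]);
    net.M = to_f(as<arma::mat>(arch["M"]));
    net.P = net.U.n_cols;
    if (net.head_kind == HEAD_STACKED) {
      net.Ugg = to_f(as<arma::mat>(params["Ugg"]));
      net.bgg = to_fv(as<arma::vec>(params["bgg"]));
      net.Mgg = to_f(as<arma::mat>(arch["Mgg"]));
    }
  }
  return net;
}

// intermediates needed for the backward pass
struct Cache {
  fm A1;            // (B*G) x H1
  fv gact;          // B*G
  fm Ag;            // B x G (post gene dropout during training)
  fm AgRaw;         // pre-dropout
  fm A2, A2Raw;     // stacked layer
  fm Hact, HactRaw; // hidden layer
  fv score, p;
  fm dmask_g, dmask_h;
};

static void forward_batch(const Net& net, const fm& Xb, int B,
                          Cache& cc, bool training,
                          float drop_gene, float drop_hidden,
                          std::mt19937_64* rng) {
  cc.A1 = Xb * net.W1;
  add_col_bias(cc.A1, net.b1);
  act_fwd_inplace(cc.A1, net.act_gene);
  // the gene output neuron is linear by default, so the gene activation G_i
  // preserves the dynamic range of the burden for downstream thresholding;
  // a bounded (tanh) gene output is available per spec
  cc.gact = cc.A1 * net.w2 + net.b2;
  if (net.act_gene_out) {
    float* p = cc.gact.memptr();
    for (arma::uword i = 0; i < cc.gact.n_elem; ++i) p[i] = fast_tanh(p[i]);
  }
  cc.AgRaw = fm(cc.gact.memptr(), B, net.G); // column per gene
  cc.Ag = cc.AgRaw;
  if (training && drop_gene > 0.0f) {
    std::bernoulli_distribution keep(1.0 - drop_gene);
    cc.dmask_g.set_size(B, net.G);
    for (arma::uword j = 0; j < cc.dmask_g.n_elem; ++j)
      cc.dmask_g(j) = keep(*rng) ? 1.0f / (1.0f - drop_gene) : 0.0f;
    cc.Ag %= cc.dmask_g;
  }
  const fm* in = &cc.Ag;
  if (net.head_kind == HEAD_LOGREG) {
    cc.score = cc.Ag * net.v + net.c_out;
  } else {
    if (net.head_kind == HEAD_STACKED) {
      fm Wgg = net.Mgg % net.Ugg;
      cc.A2Raw = cc.Ag * Wgg;
      add_col_bias(cc.A2Raw, net.bgg);
      act_fwd_inplace(cc.A2Raw, net.act_hidden);
      cc.A2 = cc.A2Raw;
      in = &cc.A2;
    }
    fm Weff = net.M % net.U;
    cc.HactRaw = (*in) * Weff;
    add_col_bias(cc.HactRaw, net.bh);
    act_fwd_inplace(cc.HactRaw, net.act_hidden);
    cc.Hact = cc.HactRaw;
    if (training && drop_hidden > 0.0f) {
      std::bernoulli_distribution keep(1.0 - drop_hidden);
      cc.dmask_h.set_size(B, net.P);
      for (arma::uword j = 0; j < cc.dmask_h.n_elem; ++j)
        cc.dmask_h(j) = keep(*rng) ? 1.0f / (1.0f - drop_hidden) : 0.0f;
      cc.Hact %= cc.dmask_h;
    }
    cc.score = cc.Hact * net.w + net.c_out;
  }
  cc.p = 1.0f / (1.0f + arma::exp(-cc.score));
}

// [[Rcpp::export]]
arma::vec nn_forward_cpp(const arma::mat& Xmat, int n, int G,
                         List params, List arch) {
  Net net = unpack(params, arch, n, G, Xmat.n_cols);
  Cache cc;
  fm Xf = to_f(Xmat);
  forward_batch(net, Xf, n, cc, false, 0.0f, 0.0f, nullptr);
  return arma::conv_to<arma::vec>::from(cc.p);
}

// stable argsort of a subset of matrix positions: primary key the value,
// tie-break on row-major (gene, hidden) order of the G x P matrix
static std::vector<arma::uword> order_idx(const std::vector<arma::uword>& idx,
                                          const fm& val, int G,
                                          bool ascending) {
  std::vector<arma::uword> out = idx;
  const arma::uword P = val.n_cols;
  std::stable_sort(out.begin(), out.end(),
    [&](arma::uword a, arma::uword b) {
      float va = val(a), vb = val(b);
      if (va != vb) return ascending ? (va < vb) : (va > vb);
      arma::uword ra = (a % G) * P + (a / G);
      arma::uword rb = (b % G) * P + (b / G);
      return ra < rb;
    });
  return out;
}

// [[Rcpp::export]]
List nn_train_cpp(const arma::mat& Xmat, const arma::vec& y, int n, int G,
                  List params, List arch, List cfg,
                  const arma::imat& perm, List riglcfg) {
  const int C = Xmat.n_cols;
  Net net = unpack(params, arch, n, G, C);
  fm Xf = to_f(Xmat);
  fv yf = to_fv(y);

  const float lr = (float)as<double>(cfg["learning_rate"]);
  const int batch = as<int>(cfg["batch_size"]);
  const int epochs = as<int>(cfg["epochs"]);
  const double alpha = as<double>(cfg["focal_alpha"]);
  const double gamma = as<double>(cfg["focal_gamma"]);
  const float wd = (float)as<double>(cfg["weight_decay"]);
  const float drop_gene = (float)as<double>(cfg["dropout_gene"]);
  const float drop_hidden = (float)as<double>(cfg["dropout_hidden"]);
  const float l1_head = (float)as<double>(cfg["l1_head"]);
  const double clamp = as<double>(cfg["clamp"]);
  const int seed = as<int>(cfg["seed"]);

  const bool rigl_on = as<bool>(riglcfg["enabled"]);
  const int rigl_interval = rigl_on ? as<int>(riglcfg["update_interval"]) : 0;
  const int rigl_stop = rigl_on ? as<int>(riglcfg["stop_iteration"]) : 0;
  const double rigl_frac = rigl_on ? as<double>(riglcfg["drop_fraction"]) : 0.0;

  std::mt19937_64 rng((uint64_t)seed);

  const float b1m = 0.9f, b2m = 0.999f, eps = 1e-8f;
  AdamState sW1(net.W1.n_rows, net.W1.n_cols), sb1(net.b1.n_elem, 1),
            sw2(net.w2.n_elem, 1), sb2(1, 1);
  AdamState sv, sc(1, 1), sU, sbh, sw, sUgg, sbgg;
  if (net.head_kind == HEAD_LOGREG) {
    sv = AdamState(net.v.n_elem, 1);
  } else {
    sU = AdamState(net.U.n_rows, net.U.n_cols);
    sbh = AdamState(net.bh.n_elem, 1);
    sw = AdamState(net.w.n_elem, 1);
    if (net.head_kind == HEAD_STACKED) {
      sUgg = AdamState(net.Ugg.n_rows, net.Ugg.n_cols);
      sbgg = AdamState(net.bgg.n_elem, 1);
    }
  }

  arma::vec history(epochs, arma::fill::zeros);
  long step = 0;
  const int n_batches = (n + batch - 1) / batch;
  Cache cc;
  fm Xb; fv yb, dscore;

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0;
    long ep_count = 0;
    for (int bi = 0; bi < n_batches; ++bi) {
      const int lo = bi * batch;
      const int hi = std::min(n, lo + batch) - 1;
      const int B = hi - lo + 1;
      // gather the batch rows for every gene
      Xb.set_size((arma::uword)B * G, C);
      yb.set_size(B);
      for (int i = 0; i < B; ++i) yb(i) = yf(perm(ep, lo + i));
      for (int c = 0; c < C; ++c) {
        const float* src = Xf.colptr(c);
        float* dst = Xb.colptr(c);
        for (int g = 0; g < G; ++g) {
          const float* sg = src + (size_t)g * n;
          float* dg = dst + (size_t)g * B;
          for (int i = 0; i < B; ++i) dg[i] = sg[perm(ep, lo + i)];
        }
      }

      forward_batch(net, Xb, B, cc, true, drop_gene, drop_hidden, &rng);
      dscore.set_size(B);
      double loss = focal_loss_and_grad(cc.p, yb, alpha, gamma, clamp, dscore);
      if (!std::isfinite(loss))
        stop("non-finite training loss at epoch %d, batch %d", ep + 1, bi + 1);
      ep_loss += loss * B;
      ep_count += B;

      const float bc1 = 1.0f - std::pow(b1m, (float)(step + 1));
      const float bc2 = 1.0f - std::pow(b2m, (float)(step + 1));

      // ---- backward ----
      fm dAg;           // B x G, gradient wrt (dropped) Ag
      fm gU_dense;      // kept for the RigL grow criterion
      float gc = arma::accu(dscore);
      if (net.head_kind == HEAD_LOGREG) {
        fm gv = cc.Ag.t() * dscore + wd * net.v;
        dAg = dscore * net.v.t();
        { fm t(net.v.memptr(), net.v.n_elem, 1, false, true);
          adam_step(t, gv, sv, lr, b1m, b2m, eps, bc1, bc2); }
        fm gcm(1, 1); gcm(0, 0) = gc;
        fm cm(1, 1); cm(0, 0) = net.c_out;
        adam_step(cm, gcm, sc, lr, b1m, b2m, eps, bc1, bc2);
        net.c_out = cm(0, 0);
      } else {
        const fm& in = (net.head_kind == HEAD_STACKED) ? cc.A2 : cc.Ag;
        fm gw = cc.Hact.t() * dscore + wd * net.w;
        fm dHpre = dscore * net.w.t();              // wrt dropped Hact
        if (drop_hidden > 0.0f) dHpre %= cc.dmask_h; // wrt raw Hact
        act_bwd_inplace(dHpre, cc.HactRaw, net.act_hidden);
        gU_dense = in.t() * dHpre;
        fm gU = gU_dense % net.M + wd * net.U;
        if (l1_head > 0.0f) gU += l1_head * arma::sign(net.U) % net.M;
        fv gbh = arma::sum(dHpre, 0).t();
        fm dIn = dHpre * (net.M % net.U).t();
        adam_step(net.U, gU, sU, lr, b1m, b2m, eps, bc1, bc2);
        net.U %= net.M; // keep masked-out entries structurally zero
        { fm t(net.bh.memptr(), net.bh.n_elem, 1, false, true);
          adam_step(t, gbh, sbh, lr, b1m, b2m, eps, bc1, bc2); }
        { fm t(net.w.memptr(), net.w.n_elem, 1, false, true);
          adam_step(t, gw, sw, lr, b1m, b2m, eps, bc1, bc2); }
        fm gcm(1, 1); gcm(0, 0) = gc;
        fm cm(1, 1); cm(0, 0) = net.c_out;
        adam_step(cm, gcm, sc, lr, b1m, b2m, eps, bc1, bc2);
        net.c_out = cm(0, 0);
        if (net.head_kind == HEAD_STACKED) {
          fm dA2pre = std::move(dIn);
          act_bwd_inplace(dA2pre, cc.A2Raw, net.act_hidden);
          fm gUgg = (cc.Ag.t() * dA2pre) % net.Mgg + wd * net.Ugg;
          fv gbgg = arma::sum(dA2pre, 0).t();
          dAg = dA2pre * (net.Mgg % net.Ugg).t();
          adam_step(net.Ugg, gUgg, sUgg, lr, b1m, b2m, eps, bc1, bc2);
          net.Ugg %= net.Mgg;
          fm t(net.bgg.memptr(), net.bgg.n_elem, 1, false, true);
          adam_step(t, gbgg, sbgg, lr, b1m, b2m, eps, bc1, bc2);
        } else {
          dAg = std::move(dIn);
        }

        // ---- RigL mask update (drop lowest |U|, grow largest |grad|) ----
        if (rigl_on && rigl_interval > 0 && (step + 1) % rigl_interval == 0 &&
            (step + 1) <= rigl_stop) {
          // cosine-annealed drop fraction
          double t_frac = (double)(step + 1) / (double)rigl_stop;
          double f = 0.5 * rigl_frac * (1.0 + std::cos(M_PI * t_frac));
          std::vector<arma::uword> active, inactive;
          for (arma::uword j = 0; j < net.M.n_elem; ++j)
            (net.M(j) > 0.5f ? active : inactive).push_back(j);
          arma::uword kdrop = (arma::uword)std::floor(f * active.size());
          kdrop = std::min(kdrop, (arma::uword)inactive.size());
          if (kdrop > 0) {
            fm absU = arma::abs(net.U);
            std::vector<arma::uword> dropv = order_idx(active, absU, G, true);
            fm absG = arma::abs(gU_dense);
            std::vector<arma::uword> growv =
              order_idx(inactive, absG, G, false);
            for (arma::uword t2 = 0; t2 < kdrop; ++t2) {
              arma::uword d = dropv[t2], gr = growv[t2];
              net.M(d) = 0.0f; net.U(d) = 0.0f;
              sU.m(d) = 0.0f; sU.v(d) = 0.0f;
              net.M(gr) = 1.0f; net.U(gr) = 0.0f;
              sU.m(gr) = 0.0f; sU.v(gr) = 0.0f;
            }
          }
        }
      }
      // gene dropout backward, then into the shared gene module
      if (drop_gene > 0.0f) dAg %= cc.dmask_g;
      fv dgact(dAg.memptr(), (arma::uword)B * G); // column-major match
      if (net.act_gene_out) {
        float* d = dgact.memptr();
        const float* a = cc.gact.memptr();
        for (arma::uword i = 0; i < dgact.n_elem; ++i)
          d[i] *= (1.0f - a[i] * a[i]);
      }
      fm gw2 = cc.A1.t() * dgact + wd * net.w2;
      float gb2 = arma::accu(dgact);
      fm dA1 = dgact * net.w2.t();
      act_bwd_inplace(dA1, cc.A1, net.act_gene);
      fm gW1 = Xb.t() * dA1 + wd * net.W1;
      fv gb1 = arma::sum(dA1, 0).t();
      adam_step(net.W1, gW1, sW1, lr, b1m, b2m, eps, bc1, bc2);
      { fm t(net.b1.memptr(), net.b1.n_elem, 1, false, true);
        adam_step(t, gb1, sb1, lr, b1m, b2m, eps, bc1, bc2); }
      { fm t(net.w2.memptr(), net.w2.n_elem, 1, false, true);
        adam_step(t, gw2, sw2, lr, b1m, b2m, eps, bc1, bc2); }
      { fm gcm(1, 1); gcm(0, 0) = gb2;
        fm cm(1, 1); cm(0, 0) = net.b2;
        adam_step(cm, gcm, sb2, lr, b1m, b2m, eps, bc1, bc2);
        net.b2 = cm(0, 0); }
      ++step;
    }
    history(ep) = ep_loss / (double)ep_count;
  }

  List out_params = List::create(
    Named("W1") = to_d(net.W1), Named("b1") = to_d(net.b1),
    Named("w2") = to_d(net.w2), Named("b2") = (double)net.b2);
  if (net.head_kind == HEAD_LOGREG) {
    out_params["v"] = to_d(net.v); out_params["c"] = (double)net.c_out;
  } else {
    out_params["U"] = to_d(net.U); out_params["bh"] = to_d(net.bh);
    out_params["w"] = to_d(net.w); out_params["c"] = (double)net.c_out;
    if (net.head_kind == HEAD_STACKED) {
      out_params["Ugg"] = to_d(net.Ugg); out_params["bgg"] = to_d(net.bgg);
    }
  }
  return List::create(Named("params") = out_params,
                      Named("history") = history,
                      Named("n_steps") = (double)step,
                      Named("mask") = to_d(net.M));
}
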