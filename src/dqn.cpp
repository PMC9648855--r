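// Convolutional dueling double deep Q-network.
//
// The network follows the fixed architecture: three 5x5 convolutional
// layers with 32, 64 and 64 filters on the 12 x 48 x 3 panoramic
// observation, a fully connected layer with 50 rectified units (the
// analysis layer, with optional dropout during training), and a dueling
// head that combines a scalar state value V with per-action advantages A
// into Q = V + A - mean(A). Targets use the double-Q rule: the online
// network chooses the argmax action at s', the target network evaluates
// it. Optimization is Adam on the squared TD error of the chosen action.
//
// The core runs in single precision (the arithmetic is BLAS-bound and
// float doubles the throughput; Q-learning is indifferent to the last
// digits); the R interface converts at the boundary.
//
// Observations are column-major flattenings of R arrays dim c(12, 48, 3):
// flat index = row + 12*col + 576*channel (0-based).
//
// All randomness (weight init, dropout masks, lesion noise) is drawn from
// R's RNG so that set.seed() in R makes every result reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

typedef arma::fmat FMat;
typedef arma::fvec FVec;
typedef arma::frowvec FRow;

static FMat to_f(const arma::mat& m) { return arma::conv_to<FMat>::from(m); }
static arma::mat to_d(const FMat& m) { return arma::conv_to<arma::mat>::from(m); }
static arma::vec to_dv(const FVec& v) { return arma::conv_to<arma::vec>::from(v); }
static FVec to_fv(const arma::vec& v) { return arma::conv_to<FVec>::from(v); }

struct ConvGeom {
  int Hin, Win, Cin, F;   // input height/width/channels, filter count
  int sh, sw, ph;         // vertical stride, horizontal stride, vertical pad
  int Hout, Wout, K;      // output dims, kernel vector length (25*Cin)
};

static ConvGeom make_geom(int Hin, int Win, int Cin, int F, int sh, int sw, int ph) {
  ConvGeom g;
  g.Hin = Hin; g.Win = Win; g.Cin = Cin; g.F = F;
  g.sh = sh; g.sw = sw; g.ph = ph;
  g.Hout = (Hin + 2 * ph - 5) / sh + 1;
  g.Wout = (Win - 5) / sw + 1;
  g.K = 25 * Cin;
  return g;
}

// layout within one batch column: idx = f*H*W + w*H + h
// the innermost kernel-row run (kh = 0..4) is contiguous in both the
// patch column and the input column, so it is copied as a block except
// where vertical zero-padding intrudes
static void im2col(const FMat& X, const ConvGeom& g, FMat& P) {
  const int B = X.n_cols;
  P.set_size(g.K, (size_t)g.Hout * g.Wout * B);
  for (int b = 0; b < B; ++b) {
    for (int ow = 0; ow < g.Wout; ++ow) {
      for (int oh = 0; oh < g.Hout; ++oh) {
        const size_t col = ((size_t)b * g.Wout + ow) * g.Hout + oh;
        float* pc = P.colptr(col);
        const int ih0 = oh * g.sh - g.ph;  // input row of kh = 0
        const int k_lo = std::max(0, -ih0);
        const int k_hi = std::min(5, g.Hin - ih0);
        for (int cin = 0; cin < g.Cin; ++cin) {
          const float* xc = X.colptr(b) + (size_t)cin * g.Hin * g.Win;
          for (int kw = 0; kw < 5; ++kw) {
            const int iw = ow * g.sw + kw;
            float* dst = pc + (cin * 5 + kw) * 5;
            const float* src = xc + (size_t)iw * g.Hin + ih0;
            if (k_lo <= 0 && k_hi >= 5) {
              dst[0] = src[0]; dst[1] = src[1]; dst[2] = src[2];
              dst[3] = src[3]; dst[4] = src[4];
            } else {
              for (int kh = 0; kh < 5; ++kh)
                dst[kh] = (kh >= k_lo && kh < k_hi) ? src[kh] : 0.0f;
            }
          }
        }
      }
    }
  }
}

static void col2im(const FMat& dP, const ConvGeom& g, FMat& dX) {
  const int B = dX.n_cols;
  dX.zeros();
  for (int b = 0; b < B; ++b) {
    for (int ow = 0; ow < g.Wout; ++ow) {
      for (int oh = 0; oh < g.Hout; ++oh) {
        const size_t col = ((size_t)b * g.Wout + ow) * g.Hout + oh;
        const float* pc = dP.colptr(col);
        const int ih0 = oh * g.sh - g.ph;
        const int k_lo = std::max(0, -ih0);
        const int k_hi = std::min(5, g.Hin - ih0);
        for (int cin = 0; cin < g.Cin; ++cin) {
          float* xc = dX.colptr(b) + (size_t)cin * g.Hin * g.Win;
          for (int kw = 0; kw < 5; ++kw) {
            const int iw = ow * g.sw + kw;
            const float* src = pc + (cin * 5 + kw) * 5;
            float* dst = xc + (size_t)iw * g.Hin + ih0;
            for (int kh = k_lo; kh < k_hi; ++kh) dst[kh] += src[kh];
          }
        }
      }
    }
  }
}

// reshape conv output Z (F x Hout*Wout*B) to layer layout (F*Hout*Wout x B)
static void repack_fwd(const FMat& Z, const ConvGeom& g, FMat& Y) {
  const int B = Z.n_cols / ((size_t)g.Hout * g.Wout);
  const size_t HW = (size_t)g.Hout * g.Wout;
  Y.set_size(HW * g.F, B);
  for (int b = 0; b < B; ++b) {
    float* yc = Y.colptr(b);
    for (size_t p = 0; p < HW; ++p) {
      const float* zc = Z.colptr((size_t)b * HW + p);
      for (int f = 0; f < g.F; ++f) yc[(size_t)f * HW + p] = zc[f];
    }
  }
}

static void repack_bwd(const FMat& dY, const ConvGeom& g, FMat& dZ) {
  const int B = dY.n_cols;
  const size_t HW = (size_t)g.Hout * g.Wout;
  dZ.set_size(g.F, HW * B);
  for (int b = 0; b < B; ++b) {
    const float* yc = dY.colptr(b);
    for (size_t p = 0; p < HW; ++p) {
      float* zc = dZ.colptr((size_t)b * HW + p);
      for (int f = 0; f < g.F; ++f) zc[f] = yc[(size_t)f * HW + p];
    }
  }
}

struct Params {
  FMat W1, W2, W3, W4, Wv, Wa;
  FVec b1, b2, b3, b4, bv, ba;
};

struct AdamState {
  Params m, v;
  long t = 0;
};

struct FwdCache {
  FMat P1, P2, P3;      // im2col matrices
  FMat Z1, Z2, Z3;      // conv pre-activations (F x HWB)
  FMat Y1, Y2, Y3;      // rectified conv outputs in layer layout
  FMat Hpre, H;         // fc pre-activation / post-relu (+dropout)
  FMat mask;            // dropout mask (scaled), empty if unused
};

static FMat relu(const FMat& m) {
  FMat r = m;
  r.transform([](float x) { return x > 0.0f ? x : 0.0f; });
  return r;
}

class DQN {
 public:
  ConvGeom g1, g2, g3;
  int n_actions;
  double dropout_rate;
  int sync_interval = 100;
  long train_steps = 0;
  Params online, target;
  AdamState adam;

  DQN(int nA, double dropout) : n_actions(nA), dropout_rate(dropout) {
    g1 = make_geom(12, 48, 3, 32, 2, 2, 0);              // -> 4 x 22 x 32
    g2 = make_geom(g1.Hout, g1.Wout, 32, 64, 2, 2, 2);    // -> 2 x 9 x 64
    g3 = make_geom(g2.Hout, g2.Wout, 64, 64, 1, 2, 2);    // -> 2 x 3 x 64
    init_params();
    target = online;
  }

  int flat_dim() const { return g3.F * g3.Hout * g3.Wout; }

  void init_params() {
    online.W1 = he_init(g1.F, g1.K);
    online.W2 = he_init(g2.F, g2.K);
    online.W3 = he_init(g3.F, g3.K);
    online.W4 = he_init(50, flat_dim());
    online.Wv = he_init(1, 50);
    online.Wa = he_init(n_actions, 50);
    online.b1.zeros(g1.F); online.b2.zeros(g2.F); online.b3.zeros(g3.F);
    online.b4.zeros(50); online.bv.zeros(1); online.ba.zeros(n_actions);
    zero_like(adam.m); zero_like(adam.v);
    adam.t = 0;
  }

  FMat he_init(int rows, int cols) {
    NumericVector z = rnorm(rows * cols, 0.0, std::sqrt(2.0 / cols));
    FMat w(rows, cols);
    for (int i = 0; i < rows * cols; ++i) w(i) = (float)z[i];
    return w;
  }

  void zero_like(Params& p) {
    p.W1.zeros(arma::size(online.W1)); p.W2.zeros(arma::size(online.W2));
    p.W3.zeros(arma::size(online.W3)); p.W4.zeros(arma::size(online.W4));
    p.Wv.zeros(arma::size(online.Wv)); p.Wa.zeros(arma::size(online.Wa));
    p.b1.zeros(arma::size(online.b1)); p.b2.zeros(arma::size(online.b2));
    p.b3.zeros(arma::size(online.b3)); p.b4.zeros(arma::size(online.b4));
    p.bv.zeros(arma::size(online.bv)); p.ba.zeros(arma::size(online.ba));
  }

  // forward pass; dropout applied only when train && dropout_rate > 0
  FMat forward(const Params& p, const FMat& obs, bool train,
               FwdCache* cache) const {
    FwdCache local;
    FwdCache& c = cache ? *cache : local;
    im2col(obs, g1, c.P1);
    c.Z1 = p.W1 * c.P1;
    c.Z1.each_col() += p.b1;
    repack_fwd(relu(c.Z1), g1, c.Y1);
    im2col(c.Y1, g2, c.P2);
    c.Z2 = p.W2 * c.P2;
    c.Z2.each_col() += p.b2;
    repack_fwd(relu(c.Z2), g2, c.Y2);
    im2col(c.Y2, g3, c.P3);
    c.Z3 = p.W3 * c.P3;
    c.Z3.each_col() += p.b3;
    repack_fwd(relu(c.Z3), g3, c.Y3);
    c.Hpre = p.W4 * c.Y3;
    c.Hpre.each_col() += p.b4;
    c.H = relu(c.Hpre);
    if (train && dropout_rate > 0) {
      NumericVector u = runif(c.H.n_elem);
      c.mask.set_size(arma::size(c.H));
      const float keep = 1.0f - (float)dropout_rate;
      for (size_t i = 0; i < c.H.n_elem; ++i)
        c.mask(i) = ((float)u[i] < keep) ? 1.0f / keep : 0.0f;
      c.H %= c.mask;
    } else {
      c.mask.reset();
    }
    return duel(p, c.H);
  }

  FMat duel(const Params& p, const FMat& H) const {
    FMat V = p.Wv * H;             // 1 x B
    V.each_col() += p.bv;
    FMat A = p.Wa * H;             // nA x B
    A.each_col() += p.ba;
    FRow Am = arma::mean(A, 0);
    A.each_row() -= Am;
    A.each_row() += V.row(0);
    return A;
  }

  // hidden-layer activations in evaluation mode (pre lesion noise)
  FMat hidden(const FMat& obs) const {
    FwdCache c;
    forward(online, obs, false, &c);
    return c.H;
  }

  arma::vec td_targets(const FMat& obs_next, const arma::vec& rewards,
                       const arma::uvec& terminal, double gamma) const {
    arma::vec y = rewards;
    arma::uvec live = arma::find(terminal == 0);
    if (live.n_elem > 0) {
      FMat on = forward(online, obs_next.cols(live), false, nullptr);
      FMat tg = forward(target, obs_next.cols(live), false, nullptr);
      for (size_t k = 0; k < live.n_elem; ++k) {
        arma::uword astar;
        on.col(k).max(astar);
        y(live(k)) += gamma * (double)tg(astar, k);
      }
    }
    return y;
  }

  // gradients of mean squared TD error wrt online params, for frozen
  // targets y and chosen 0-based actions; returns loss. 'train' controls
  // dropout (enabled during learning, disabled for gradient audits).
  double gradients(const FMat& obs, const arma::uvec& actions,
                   const arma::vec& y, bool train, Params& gr) {
    const int B = obs.n_cols;
    FwdCache c;
    FMat Q = forward(online, obs, train, &c);
    FMat dQ(n_actions, B, arma::fill::zeros);
    double loss = 0.0;
    for (int b = 0; b < B; ++b) {
      const double d = (double)Q(actions(b), b) - y(b);
      loss += d * d;
      dQ(actions(b), b) = (float)(2.0 * d / B);
    }
    loss /= B;

    // dueling head backward: dV = colsum(dQ); dA = dQ - colmean(dQ)
    FRow dV = arma::sum(dQ, 0);
    FMat dA = dQ;
    dA.each_row() -= arma::mean(dQ, 0);
    gr.Wv = dV * c.H.t();
    gr.bv = FVec{arma::accu(dV)};
    gr.Wa = dA * c.H.t();
    gr.ba = arma::sum(dA, 1);
    FMat dH = online.Wv.t() * dV + online.Wa.t() * dA;
    if (c.mask.n_elem > 0) dH %= c.mask;
    dH %= arma::conv_to<FMat>::from(c.Hpre > 0);
    gr.W4 = dH * c.Y3.t();
    gr.b4 = arma::sum(dH, 1);
    FMat dY3 = online.W4.t() * dH;

    conv_backward(dY3, c.Z3, c.P3, c.Y2, online.W3, g3, gr.W3, gr.b3, &dY3);
    conv_backward(dY3, c.Z2, c.P2, c.Y1, online.W2, g2, gr.W2, gr.b2, &dY3);
    conv_backward(dY3, c.Z1, c.P1, obs, online.W1, g1, gr.W1, gr.b1, nullptr);
    return loss;
  }

  void conv_backward(const FMat& dY, const FMat& Z, const FMat& P,
                     const FMat& Xin, const FMat& W, const ConvGeom& g,
                     FMat& dW, FVec& db, FMat* dXout) {
    FMat dZ;
    repack_bwd(dY, g, dZ);
    dZ %= arma::conv_to<FMat>::from(Z > 0);
    dW = dZ * P.t();
    db = arma::sum(dZ, 1);
    if (dXout) {
      FMat dP = W.t() * dZ;
      FMat dX(Xin.n_rows, Xin.n_cols);
      col2im(dP, g, dX);
      *dXout = dX;
    }
  }

  void adam_update(const Params& gr, double lr) {
    adam.t += 1;
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    const float c1 = 1.0f - std::pow(b1, (float)adam.t);
    const float c2 = 1.0f - std::pow(b2, (float)adam.t);
    const float flr = (float)lr;
    auto upd = [&](FMat& w, FMat& m, FMat& v, const FMat& g) {
      m = b1 * m + (1 - b1) * g;
      v = b2 * v + (1 - b2) * arma::square(g);
      w -= flr * (m / c1) / (arma::sqrt(v / c2) + eps);
    };
    auto updv = [&](FVec& w, FVec& m, FVec& v, const FVec& g) {
      m = b1 * m + (1 - b1) * g;
      v = b2 * v + (1 - b2) * arma::square(g);
      w -= flr * (m / c1) / (arma::sqrt(v / c2) + eps);
    };
    upd(online.W1, adam.m.W1, adam.v.W1, gr.W1);
    upd(online.W2, adam.m.W2, adam.v.W2, gr.W2);
    upd(online.W3, adam.m.W3, adam.v.W3, gr.W3);
    upd(online.W4, adam.m.W4, adam.v.W4, gr.W4);
    upd(online.Wv, adam.m.Wv, adam.v.Wv, gr.Wv);
    upd(online.Wa, adam.m.Wa, adam.v.Wa, gr.Wa);
    updv(online.b1, adam.m.b1, adam.v.b1, gr.b1);
    updv(online.b2, adam.m.b2, adam.v.b2, gr.b2);
    updv(online.b3, adam.m.b3, adam.v.b3, gr.b3);
    updv(online.b4, adam.m.b4, adam.v.b4, gr.b4);
    updv(online.bv, adam.m.bv, adam.v.bv, gr.bv);
    updv(online.ba, adam.m.ba, adam.v.ba, gr.ba);
  }
};

static DQN* get(SEXP ptr) {
  Rcpp::XPtr<DQN> xp(ptr);
  return xp.get();
}

// [[Rcpp::export]]
SEXP dqn_create(int n_actions, double dropout_rate) {
  if (n_actions < 1) stop("n_actions must be positive");
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)");
  Rcpp::XPtr<DQN> ptr(new DQN(n_actions, dropout_rate), true);
  return ptr;
}

// [[Rcpp::export]]
int dqn_num_actions(SEXP net) { return get(net)->n_actions; }

// [[Rcpp::export]]
void dqn_set_sync_interval(SEXP net, int interval) {
  if (interval < 1) stop("sync interval must be positive");
  get(net)->sync_interval = interval;
}

// [[Rcpp::export]]
void dqn_sync_target(SEXP net) { get(net)->target = get(net)->online; }

// [[Rcpp::export]]
arma::mat dqn_qvalues(SEXP net, const arma::mat& obs) {
  DQN* d = get(net);
  return to_d(d->forward(d->online, to_f(obs), false, nullptr));
}

// [[Rcpp::export]]
arma::mat dqn_hidden(SEXP net, const arma::mat& obs) {
  return to_d(get(net)->hidden(to_f(obs)));
}

// Q-values with lesion noise injected into the 50-unit layer: each
// targeted unit (0-based) receives an independent draw from a zero-mean
// normal whose sd is noise_scale times the maximum activation of the
// layer on that forward pass. noise_scale = 0 draws nothing.
// [[Rcpp::export]]
arma::mat dqn_qvalues_lesioned(SEXP net, const arma::mat& obs,
                               const arma::uvec& units, double noise_scale) {
  DQN* d = get(net);
  FMat H = d->hidden(to_f(obs));
  if (noise_scale > 0) {
    if (units.n_elem == 0) stop("empty lesion target with positive noise scale");
    for (size_t b = 0; b < H.n_cols; ++b) {
      const double sd = noise_scale * (double)H.col(b).max();
      if (sd > 0) {
        NumericVector z = rnorm(units.n_elem, 0.0, sd);
        for (size_t k = 0; k < units.n_elem; ++k) H(units(k), b) += (float)z[k];
      }
    }
  }
  return to_d(d->duel(d->online, H));
}

// [[Rcpp::export]]
arma::vec dqn_td_targets(SEXP net, const arma::mat& obs_next,
                         const arma::vec& rewards, const arma::uvec& terminal,
                         double gamma) {
  return get(net)->td_targets(to_f(obs_next), rewards, terminal, gamma);
}

// One replay update: compute double-Q targets, take one Adam step on the
// squared TD error of the chosen (1-based) actions, and sync the target
// network every sync_interval updates. Returns the minibatch loss.
// [[Rcpp::export]]
double dqn_train_batch(SEXP net, const arma::mat& obs, const arma::mat& obs_next,
                       const arma::uvec& actions, const arma::vec& rewards,
                       const arma::uvec& terminal, double gamma, double lr) {
  DQN* d = get(net);
  FMat fobs = to_f(obs);
  arma::vec y = d->td_targets(to_f(obs_next), rewards, terminal, gamma);
  Params gr;
  double loss = d->gradients(fobs, actions - 1, y, true, gr);
  if (!std::isfinite(loss)) stop("training diverged: non-finite TD loss");
  d->adam_update(gr, lr);
  d->train_steps += 1;
  if (d->train_steps % d->sync_interval == 0) d->target = d->online;
  return loss;
}

// Loss and gradients with frozen targets y (no dropout); for audits.
// [[Rcpp::export]]
double dqn_loss_given_targets(SEXP net, const arma::mat& obs,
                              const arma::uvec& actions, const arma::vec& y) {
  DQN* d = get(net);
  FMat Q = d->forward(d->online, to_f(obs), false, nullptr);
  double loss = 0.0;
  for (size_t b = 0; b < obs.n_cols; ++b) {
    const double diff = (double)Q(actions(b) - 1, b) - y(b);
    loss += diff * diff;
  }
  return loss / obs.n_cols;
}

// [[Rcpp::export]]
List dqn_gradients_given_targets(SEXP net, const arma::mat& obs,
                                 const arma::uvec& actions, const arma::vec& y) {
  DQN* d = get(net);
  Params gr;
  d->gradients(to_f(obs), actions - 1, y, false, gr);
  return List::create(
    _["W1"] = to_d(gr.W1), _["b1"] = to_dv(gr.b1),
    _["W2"] = to_d(gr.W2), _["b2"] = to_dv(gr.b2),
    _["W3"] = to_d(gr.W3), _["b3"] = to_dv(gr.b3),
    _["W4"] = to_d(gr.W4), _["b4"] = to_dv(gr.b4),
    _["Wv"] = to_d(gr.Wv), _["bv"] = to_dv(gr.bv),
    _["Wa"] = to_d(gr.Wa), _["ba"] = to_dv(gr.ba));
}

// [[Rcpp::export]]
List dqn_get_params(SEXP net) {
  const Params& p = get(net)->online;
  return List::create(
    _["W1"] = to_d(p.W1), _["b1"] = to_dv(p.b1),
    _["W2"] = to_d(p.W2), _["b2"] = to_dv(p.b2),
    _["W3"] = to_d(p.W3), _["b3"] = to_dv(p.b3),
    _["W4"] = to_d(p.W4), _["b4"] = to_dv(p.b4),
    _["Wv"] = to_d(p.Wv), _["bv"] = to_dv(p.bv),
    _["Wa"] = to_d(p.Wa), _["ba"] = to_dv(p.ba));
}

// [[Rcpp::export]]
void dqn_set_params(SEXP net, List params, bool sync = true) {
  DQN* d = get(net);
  Params& p = d->online;
  p.W1 = to_f(as<arma::mat>(params["W1"])); p.b1 = to_fv(as<arma::vec>(params["b1"]));
  p.W2 = to_f(as<arma::mat>(params["W2"])); p.b2 = to_fv(as<arma::vec>(params["b2"]));
  p.W3 = to_f(as<arma::mat>(params["W3"])); p.b3 = to_fv(as<arma::vec>(params["b3"]));
  p.W4 = to_f(as<arma::mat>(params["W4"])); p.b4 = to_fv(as<arma::vec>(params["b4"]));
  p.Wv = to_f(as<arma::mat>(params["Wv"])); p.bv = to_fv(as<arma::vec>(params["bv"]));
  p.Wa = to_f(as<arma::mat>(params["Wa"])); p.ba = to_fv(as<arma::vec>(params["ba"]));
  if (sync) d->target = p;
}

// geometry of the conv stack, for documentation and tests
// [[Rcpp::export]]
List dqn_geometry(SEXP net) {
  DQN* d = get(net);
  auto gl = [](const ConvGeom& g) {
    return List::create(_["Hout"] = g.Hout, _["Wout"] = g.Wout, _["F"] = g.F,
                        _["sh"] = g.sh, _["sw"] = g.sw, _["ph"] = g.ph);
  };
  return List::create(_["conv1"] = gl(d->g1), _["conv2"] = gl(d->g2),
                      _["conv3"] = gl(d->g3), _["flat"] = d->flat_dim(),
                      _["fc"] = 50, _["n_actions"] = d->n_actions);
}

// in-place column write into a preallocated buffer matrix (avoids R's
// copy-on-modify for large replay buffers)
// [[Rcpp::export]]
void fill_column(NumericMatrix m, int col, const NumericVector& v) {
  if (col < 1 || col > m.ncol()) stop("column out of range");
  if (v.size() != m.nrow()) stop("length mismatch");
  std::copy(v.begin(), v.end(), m.column(col - 1).begin());
}
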