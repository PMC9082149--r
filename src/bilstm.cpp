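// Bidirectional LSTM sequence regressor: one BiLSTM layer (H units per
// direction, sequence output) followed by a per-timestep dense map to one
// output. Scalar input per timestep. Trained by backpropagation through
// time with Adam, batch size 1, optional L1/L2 regularization on the
// input kernels (Keras kernel_regularizer semantics: input-to-hidden
// weights only).
//
// Parameter vector layout (H = hidden units, G = 4H gate rows, order
// i, f, g, o):
//   per direction d in {forward, backward}:
//     Wx[G]      input kernel (scalar input)
//     Wh[G x H]  recurrent kernel, row-major by gate row
//     b[G]       bias
//   dense: Wd[2H], bd[1]
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline double sigm(double z) { return 1.0 / (1.0 + std::exp(-z)); }

static int n_params(int H) { return 2 * (4 * H * (H + 2)) + 2 * H + 1; }

struct ParamView {
  double *Wx[2], *Wh[2], *b[2], *Wd, *bd;
  int H, G;
  ParamView(double *p, int H_) : H(H_), G(4 * H_) {
    int per_dir = G + G * H + G;
    for (int d = 0; d < 2; ++d) {
      double *base = p + d * per_dir;
      Wx[d] = base;
      Wh[d] = base + G;
      b[d] = base + G + G * H;
    }
    Wd = p + 2 * per_dir;
    bd = Wd + 2 * H;
  }
};

// caches for one direction's forward pass over T steps
struct DirCache {
  std::vector<double> i, f, g, o, c, h, tc; // each T*H; tc = tanh(c)
  void resize(int T, int H) {
    i.assign((size_t)T * H, 0.0); f = i; g = i; o = i;
    c = i; h = i; tc = i;
  }
};

// run one LSTM direction; xs is the input in processing order
static void lstm_forward(const ParamView &P, int d,
                         const std::vector<double> &xs, DirCache &C) {
  const int H = P.H, T = (int)xs.size();
  C.resize(T, H);
  std::vector<double> hprev(H, 0.0), cprev(H, 0.0);
  for (int t = 0; t < T; ++t) {
    const double x = xs[t];
    for (int u = 0; u < H; ++u) {
      double pre[4];
      for (int gt = 0; gt < 4; ++gt) {
        const int row = gt * H + u;
        double acc = P.Wx[d][row] * x + P.b[d][row];
        const double *wrow = P.Wh[d] + (size_t)row * H;
        for (int k = 0; k < H; ++k) acc += wrow[k] * hprev[k];
        pre[gt] = acc;
      }
      const double iv = sigm(pre[0]), fv = sigm(pre[1]);
      const double gv = std::tanh(pre[2]), ov = sigm(pre[3]);
      const double cv = fv * cprev[u] + iv * gv;
      const double tcv = std::tanh(cv);
      const size_t at = (size_t)t * H + u;
      C.i[at] = iv; C.f[at] = fv; C.g[at] = gv; C.o[at] = ov;
      C.c[at] = cv; C.tc[at] = tcv; C.h[at] = ov * tcv;
    }
    hprev.assign(C.h.begin() + (size_t)t * H, C.h.begin() + (size_t)(t + 1) * H);
    cprev.assign(C.c.begin() + (size_t)t * H, C.c.begin() + (size_t)(t + 1) * H);
  }
}

// backward through one direction; dh_out[t*H+u] is dL/dh for that step in
// processing order; accumulates into gWx/gWh/gb
static void lstm_backward(const ParamView &P, int d,
                          const std::vector<double> &xs, const DirCache &C,
                          const std::vector<double> &dh_out,
                          double *gWx, double *gWh, double *gb) {
  const int H = P.H, T = (int)xs.size();
  std::vector<double> dh_next(H, 0.0), dc_next(H, 0.0), dpre(4 * H);
  for (int t = T - 1; t >= 0; --t) {
    for (int u = 0; u < H; ++u) {
      const size_t at = (size_t)t * H + u;
      const double dh = dh_out[at] + dh_next[u];
      const double tcv = C.tc[at];
      double dc = dh * C.o[at] * (1.0 - tcv * tcv) + dc_next[u];
      const double cprev = (t > 0) ? C.c[(size_t)(t - 1) * H + u] : 0.0;
      const double dov = dh * tcv;
      const double div = dc * C.g[at];
      const double dfv = dc * cprev;
      const double dgv = dc * C.i[at];
      dpre[0 * H + u] = div * C.i[at] * (1.0 - C.i[at]);
      dpre[1 * H + u] = dfv * C.f[at] * (1.0 - C.f[at]);
      dpre[2 * H + u] = dgv * (1.0 - C.g[at] * C.g[at]);
      dpre[3 * H + u] = dov * C.o[at] * (1.0 - C.o[at]);
      dc_next[u] = dc * C.f[at];
    }
    const double x = xs[t];
    std::fill(dh_next.begin(), dh_next.end(), 0.0);
    for (int row = 0; row < 4 * H; ++row) {
      const double dp = dpre[row];
      if (dp == 0.0) continue;
      gWx[row] += dp * x;
      gb[row] += dp;
      double *gwrow = gWh + (size_t)row * H;
      const double *wrow = P.Wh[d] + (size_t)row * H;
      if (t > 0) {
        const double *hp = &C.h[(size_t)(t - 1) * H];
        for (int k = 0; k < H; ++k) gwrow[k] += dp * hp[k];
      }
      for (int k = 0; k < H; ++k) dh_next[k] += dp * wrow[k];
    }
  }
}

// forward through the whole model for one window; fills yhat and caches
static void model_forward(const ParamView &P, const double *x, int T,
                          DirCache &Cf, DirCache &Cb,
                          std::vector<double> &yhat) {
  const int H = P.H;
  std::vector<double> xf(x, x + T), xb(T);
  for (int t = 0; t < T; ++t) xb[t] = x[T - 1 - t];
  lstm_forward(P, 0, xf, Cf);
  lstm_forward(P, 1, xb, Cb);
  yhat.assign(T, 0.0);
  for (int t = 0; t < T; ++t) {
    double acc = *P.bd;
    const double *hf = &Cf.h[(size_t)t * H];
    const double *hb = &Cb.h[(size_t)(T - 1 - t) * H];
    for (int u = 0; u < H; ++u) acc += P.Wd[u] * hf[u] + P.Wd[H + u] * hb[u];
    yhat[t] = acc;
  }
}

// loss (MSE over T + kernel penalty) and full gradient for one window
static double window_loss_grad(ParamView &P, const double *x,
                               const double *y, int T,
                               double l1, double l2,
                               std::vector<double> &grad) {
  const int H = P.H, G = 4 * H;
  DirCache Cf, Cb;
  std::vector<double> yhat;
  model_forward(P, x, T, Cf, Cb, yhat);

  double mse = 0.0;
  std::vector<double> dy(T);
  for (int t = 0; t < T; ++t) {
    const double e = yhat[t] - y[t];
    mse += e * e;
    dy[t] = 2.0 * e / T;
  }
  mse /= T;

  std::fill(grad.begin(), grad.end(), 0.0);
  ParamView Gv(grad.data(), H);

  // dense gradients and dL/dh per direction (processing order)
  std::vector<double> dhf((size_t)T * H, 0.0), dhb((size_t)T * H, 0.0);
  for (int t = 0; t < T; ++t) {
    const double d = dy[t];
    const double *hf = &Cf.h[(size_t)t * H];
    const double *hb = &Cb.h[(size_t)(T - 1 - t) * H];
    *Gv.bd += d;
    for (int u = 0; u < H; ++u) {
      Gv.Wd[u] += d * hf[u];
      Gv.Wd[H + u] += d * hb[u];
      dhf[(size_t)t * H + u] += d * P.Wd[u];
      dhb[(size_t)(T - 1 - t) * H + u] += d * P.Wd[H + u];
    }
  }
  std::vector<double> xf(x, x + T), xb(T);
  for (int t = 0; t < T; ++t) xb[t] = x[T - 1 - t];
  lstm_backward(P, 0, xf, Cf, dhf, Gv.Wx[0], Gv.Wh[0], Gv.b[0]);
  lstm_backward(P, 1, xb, Cb, dhb, Gv.Wx[1], Gv.Wh[1], Gv.b[1]);

  // kernel regularization (input kernels of both directions)
  double pen = 0.0;
  for (int d = 0; d < 2; ++d) {
    for (int r = 0; r < G; ++r) {
      const double w = P.Wx[d][r];
      pen += l1 * std::fabs(w) + l2 * w * w;
      Gv.Wx[d][r] += l1 * ((w > 0) - (w < 0)) + 2.0 * l2 * w;
    }
  }
  return mse + pen;
}

// [[Rcpp::export]]
NumericVector bilstm_init_params(int hidden_units, int seed) {
  if (hidden_units < 1) stop("hidden_units must be >= 1");
  const int H = hidden_units, G = 4 * H;
  NumericVector params(n_params(H));
  ParamView P(REAL(params), H);
  std::mt19937 rng((uint32_t)seed);
  auto glorot = [&](double *w, int n, int fan_in, int fan_out) {
    const double lim = std::sqrt(6.0 / (fan_in + fan_out));
    std::uniform_real_distribution<double> U(-lim, lim);
    for (int k = 0; k < n; ++k) w[k] = U(rng);
  };
  for (int d = 0; d < 2; ++d) {
    glorot(P.Wx[d], G, 1, G);
    glorot(P.Wh[d], G * H, H, G);
    for (int r = 0; r < G; ++r) P.b[d][r] = 0.0;
    for (int u = 0; u < H; ++u) P.b[d][H + u] = 1.0; // forget-gate bias
  }
  glorot(P.Wd, 2 * H, 2 * H, 1);
  *P.bd = 0.0;
  return params;
}

// [[Rcpp::export]]
NumericMatrix bilstm_predict(NumericVector params, int hidden_units,
                             NumericMatrix X) {
  const int H = hidden_units;
  if (params.size() != n_params(H)) stop("parameter vector has wrong length");
  ParamView P(REAL(params), H);
  const int n = X.nrow(), T = X.ncol();
  NumericMatrix out(n, T);
  DirCache Cf, Cb;
  std::vector<double> x(T), yhat;
  for (int s = 0; s < n; ++s) {
    for (int t = 0; t < T; ++t) x[t] = X(s, t);
    model_forward(P, x.data(), T, Cf, Cb, yhat);
    for (int t = 0; t < T; ++t) out(s, t) = yhat[t];
  }
  return out;
}

// [[Rcpp::export]]
List bilstm_loss_grad(NumericVector params, int hidden_units,
                      NumericVector x, NumericVector y,
                      double l1, double l2) {
  const int H = hidden_units;
  if (params.size() != n_params(H)) stop("parameter vector has wrong length");
  if (x.size() != y.size()) stop("x and y must have equal length");
  NumericVector p = clone(params);
  ParamView P(REAL(p), H);
  std::vector<double> grad(n_params(H), 0.0);
  const double loss = window_loss_grad(P, REAL(x), REAL(y), x.size(),
                                       l1, l2, grad);
  return List::create(_["loss"] = loss,
                      _["grad"] = NumericVector(grad.begin(), grad.end()));
}

static double mean_mse(const ParamView &P, const NumericMatrix &X,
                       const NumericMatrix &Y) {
  const int n = X.nrow(), T = X.ncol();
  DirCache Cf, Cb;
  std::vector<double> x(T), yhat;
  double total = 0.0;
  for (int s = 0; s < n; ++s) {
    for (int t = 0; t < T; ++t) x[t] = X(s, t);
    model_forward(P, x.data(), T, Cf, Cb, yhat);
    double mse = 0.0;
    for (int t = 0; t < T; ++t) {
      const double e = yhat[t] - Y(s, t);
      mse += e * e;
    }
    total += mse / T;
  }
  return total / n;
}

// [[Rcpp::export]]
List bilstm_train(NumericVector params, int hidden_units,
                  NumericMatrix Xtr, NumericMatrix Ytr,
                  NumericMatrix Xval, NumericMatrix Yval,
                  int max_epochs, double lr, double l1, double l2,
                  int patience, int shuffle_seed, bool shuffle) {
  const int H = hidden_units, NP = n_params(H);
  if (params.size() != NP) stop("parameter vector has wrong length");
  if (Xtr.nrow() == 0) stop("empty training set");
  if (Xtr.nrow() != Ytr.nrow() || Xtr.ncol() != Ytr.ncol())
    stop("training input/target shapes differ");
  const int n = Xtr.nrow(), T = Xtr.ncol();

  NumericVector p = clone(params);
  ParamView P(REAL(p), H);
  std::vector<double> grad(NP), m(NP, 0.0), v(NP, 0.0), x(T), y(T);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-7; // Adam defaults
  long step = 0;

  std::vector<int> order(n);
  for (int s = 0; s < n; ++s) order[s] = s;
  std::mt19937 srng((uint32_t)shuffle_seed);

  std::vector<double> train_hist, val_hist;
  std::vector<double> best_p(REAL(p), REAL(p) + NP);
  double best_val = R_PosInf;
  int best_epoch = 0, bad = 0, epochs_run = 0;

  for (int ep = 1; ep <= max_epochs; ++ep) {
    if (shuffle) std::shuffle(order.begin(), order.end(), srng);
    double ep_loss = 0.0;
    for (int si = 0; si < n; ++si) {
      const int s = order[si];
      for (int t = 0; t < T; ++t) { x[t] = Xtr(s, t); y[t] = Ytr(s, t); }
      const double loss = window_loss_grad(P, x.data(), y.data(), T,
                                           l1, l2, grad);
      if (!std::isfinite(loss))
        stop("training aborted: non-finite loss at epoch %d", ep);
      ep_loss += loss;
      ++step;
      const double corr = lr * std::sqrt(1.0 - std::pow(b2, (double)step)) /
                          (1.0 - std::pow(b1, (double)step));
      double *pp = REAL(p);
      for (int k = 0; k < NP; ++k) {
        m[k] = b1 * m[k] + (1.0 - b1) * grad[k];
        v[k] = b2 * v[k] + (1.0 - b2) * grad[k] * grad[k];
        pp[k] -= corr * m[k] / (std::sqrt(v[k]) + eps);
      }
    }
    train_hist.push_back(ep_loss / n);
    const double vl = (Xval.nrow() > 0) ? mean_mse(P, Xval, Yval)
                                        : ep_loss / n;
    val_hist.push_back(vl);
    epochs_run = ep;
    if (vl < best_val - 1e-12) {
      best_val = vl;
      best_epoch = ep;
      std::copy(REAL(p), REAL(p) + NP, best_p.begin());
      bad = 0;
    } else if (++bad >= patience && patience > 0) {
      break;
    }
    if (ep % 25 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["params"] = NumericVector(best_p.begin(), best_p.end()),
    _["train_loss"] = NumericVector(train_hist.begin(), train_hist.end()),
    _["val_loss"] = NumericVector(val_hist.begin(), val_hist.end()),
    _["best_epoch"] = best_epoch,
    _["epochs_run"] = epochs_run,
    _["best_val_loss"] = best_val);
}
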