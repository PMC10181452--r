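// Stacked LSTM sequence regressor: windowed many-to-one architecture with a
// linear output head, trained by Adam on mean squared error. Batched forward
// pass and backpropagation through time; inter-layer (non-recurrent) dropout.
// All randomness (init, shuffles, dropout masks) flows through one seeded
// mt19937 so training is bit-reproducible for a fixed seed on one platform.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct LstmWeights {
  std::vector<mat> Wx, Wh;   // per layer: (4H x F_l), (4H x H)
  std::vector<vec> b;        // per layer: 4H
  mat Wy;                    // K x H
  vec by;                    // K
};

static Rcpp::List weights_to_list(const LstmWeights& w) {
  Rcpp::List out;
  for (size_t l = 0; l < w.Wx.size(); ++l) {
    out[std::string("Wx") + std::to_string(l + 1)] = w.Wx[l];
    out[std::string("Wh") + std::to_string(l + 1)] = w.Wh[l];
    out[std::string("b") + std::to_string(l + 1)] = w.b[l];
  }
  out["Wy"] = w.Wy;
  out["by"] = w.by;
  return out;
}

static LstmWeights list_to_weights(const Rcpp::List& lst, int n_layers) {
  LstmWeights w;
  for (int l = 1; l <= n_layers; ++l) {
    w.Wx.push_back(Rcpp::as<mat>(lst[std::string("Wx") + std::to_string(l)]));
    w.Wh.push_back(Rcpp::as<mat>(lst[std::string("Wh") + std::to_string(l)]));
    w.b.push_back(Rcpp::as<vec>(lst[std::string("b") + std::to_string(l)]));
  }
  w.Wy = Rcpp::as<mat>(lst["Wy"]);
  w.by = Rcpp::as<vec>(lst["by"]);
  return w;
}

static LstmWeights init_weights(int n_features, int hidden, int n_layers,
                                int n_outputs, std::mt19937& rng) {
  LstmWeights w;
  auto glorot = [&rng](int rows, int cols) {
    double r = std::sqrt(6.0 / (rows + cols));
    std::uniform_real_distribution<double> u(-r, r);
    mat m(rows, cols);
    for (uword j = 0; j < m.n_cols; ++j)
      for (uword i = 0; i < m.n_rows; ++i) m(i, j) = u(rng);
    return m;
  };
  for (int l = 0; l < n_layers; ++l) {
    int fin = (l == 0) ? n_features : hidden;
    w.Wx.push_back(glorot(4 * hidden, fin));
    w.Wh.push_back(glorot(4 * hidden, hidden));
    vec b(4 * hidden, fill::zeros);
    b.subvec(hidden, 2 * hidden - 1).fill(1.0);  // forget-gate bias
    w.b.push_back(b);
  }
  w.Wy = glorot(n_outputs, hidden);
  w.by = vec(n_outputs, fill::zeros);
  return w;
}

// Cached per-layer, per-timestep activations needed by BPTT. `mask` slot t
// stores c_{t-1}; inter-layer dropout masks are appended to `input` after
// the T input matrices.
struct LayerCache {
  std::vector<mat> input, ig, fg, gg, og, c, h, mask;
};

// Inference-mode forward pass over a set of examples (no dropout); returns
// the output matrix (K x B).
static mat forward_batch(const LstmWeights& w, const cube& X,
                         const uvec& idx, int n_layers, int hidden) {
  const int T = X.n_rows, F = X.n_cols, B = idx.n_elem;
  const int H = hidden;
  std::vector<mat> seq(T);
  for (int t = 0; t < T; ++t) {
    mat xt(F, B);
    for (int b = 0; b < B; ++b)
      for (int f = 0; f < F; ++f) xt(f, b) = X(t, f, idx[b]);
    seq[t] = xt;
  }
  for (int l = 0; l < n_layers; ++l) {
    mat h(H, B, fill::zeros), c(H, B, fill::zeros);
    std::vector<mat> out_seq(T);
    for (int t = 0; t < T; ++t) {
      mat z = w.Wx[l] * seq[t] + w.Wh[l] * h;
      z.each_col() += w.b[l];
      mat ig = 1.0 / (1.0 + exp(-z.rows(0, H - 1)));
      mat fg = 1.0 / (1.0 + exp(-z.rows(H, 2 * H - 1)));
      mat gg = tanh(z.rows(2 * H, 3 * H - 1));
      mat og = 1.0 / (1.0 + exp(-z.rows(3 * H, 4 * H - 1)));
      c = fg % c + ig % gg;
      h = og % tanh(c);
      out_seq[t] = h;
    }
    seq = std::move(out_seq);
  }
  return w.Wy * seq[T - 1] + repmat(w.by, 1, B);
}

// Full forward + backward on one minibatch. Returns loss; accumulates
// gradients into `g` (same shapes as weights).
static double backward_batch(const LstmWeights& w, const cube& X, const mat& Y,
                             const uvec& idx, int n_layers, int hidden,
                             double dropout, std::mt19937* rng,
                             LstmWeights& g) {
  const int T = X.n_rows, F = X.n_cols, B = idx.n_elem;
  const int H = hidden, K = w.Wy.n_rows;
  std::bernoulli_distribution keep(1.0 - dropout);
  const bool use_drop = (rng != nullptr && dropout > 0);

  // ---- forward with caching ----
  std::vector<LayerCache> caches(n_layers);
  std::vector<std::vector<mat>> h_seq(n_layers);  // post-cell outputs per layer
  std::vector<mat> seq(T);
  for (int t = 0; t < T; ++t) {
    mat xt(F, B);
    for (int b = 0; b < B; ++b)
      for (int f = 0; f < F; ++f) xt(f, b) = X(t, f, idx[b]);
    seq[t] = xt;
  }
  for (int l = 0; l < n_layers; ++l) {
    mat h(H, B, fill::zeros), c(H, B, fill::zeros);
    LayerCache& cache = caches[l];
    std::vector<mat> out_seq(T);
    for (int t = 0; t < T; ++t) {
      mat z = w.Wx[l] * seq[t] + w.Wh[l] * h;
      z.each_col() += w.b[l];
      mat ig = 1.0 / (1.0 + exp(-z.rows(0, H - 1)));
      mat fg = 1.0 / (1.0 + exp(-z.rows(H, 2 * H - 1)));
      mat gg = tanh(z.rows(2 * H, 3 * H - 1));
      mat og = 1.0 / (1.0 + exp(-z.rows(3 * H, 4 * H - 1)));
      cache.input.push_back(seq[t]);
      cache.h.push_back(h);              // h_{t-1}
      mat c_prev = c;
      c = fg % c + ig % gg;
      h = og % tanh(c);
      cache.ig.push_back(ig); cache.fg.push_back(fg);
      cache.gg.push_back(gg); cache.og.push_back(og);
      cache.c.push_back(c);
      cache.mask.push_back(c_prev);      // reuse mask slot 1: c_{t-1}
      out_seq[t] = h;
    }
    h_seq[l] = out_seq;
    if (l < n_layers - 1) {
      for (int t = 0; t < T; ++t) {
        if (use_drop) {
          mat m(H, B);
          for (uword j = 0; j < m.n_cols; ++j)
            for (uword i = 0; i < m.n_rows; ++i) m(i, j) = keep(*rng) ? 1.0 : 0.0;
          cache.input.push_back(m);      // masks appended after T inputs
          out_seq[t] = out_seq[t] % m / (1.0 - dropout);
        }
      }
    }
    seq = std::move(out_seq);
  }
  mat top_mask;
  mat h_final = h_seq[n_layers - 1][T - 1];
  if (use_drop) {
    top_mask.set_size(H, B);
    for (uword j = 0; j < top_mask.n_cols; ++j)
      for (uword i = 0; i < top_mask.n_rows; ++i)
        top_mask(i, j) = keep(*rng) ? 1.0 : 0.0;
    h_final = h_final % top_mask / (1.0 - dropout);
  }
  mat yhat = w.Wy * h_final + repmat(w.by, 1, B);
  mat ysub(K, B);
  for (int b = 0; b < B; ++b) ysub.col(b) = Y.row(idx[b]).t();
  mat diff = yhat - ysub;
  double loss = accu(square(diff)) / (double)(B * K);

  // ---- backward ----
  mat dY = 2.0 * diff / (double)(B * K);
  g.Wy += dY * h_final.t();
  g.by += sum(dY, 1);
  mat dh_final = w.Wy.t() * dY;
  if (use_drop) dh_final = dh_final % top_mask / (1.0 - dropout);

  // dH[t]: external gradient arriving at layer l's output h_t
  std::vector<mat> dH(T, mat(H, B, fill::zeros));
  dH[T - 1] = dh_final;
  for (int l = n_layers - 1; l >= 0; --l) {
    LayerCache& cache = caches[l];
    std::vector<mat> dInput(T);
    mat dh_next(H, B, fill::zeros), dc_next(H, B, fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      mat dh = dH[t] + dh_next;
      const mat& ig = cache.ig[t]; const mat& fg = cache.fg[t];
      const mat& gg = cache.gg[t]; const mat& og = cache.og[t];
      const mat& ct = cache.c[t];  const mat& c_prev = cache.mask[t];
      mat tc = tanh(ct);
      mat dog = dh % tc;
      mat dc = dh % og % (1.0 - square(tc)) + dc_next;
      mat dig = dc % gg;
      mat dfg = dc % c_prev;
      mat dgg = dc % ig;
      mat dz(4 * H, B);
      dz.rows(0, H - 1)         = dig % ig % (1.0 - ig);
      dz.rows(H, 2 * H - 1)     = dfg % fg % (1.0 - fg);
      dz.rows(2 * H, 3 * H - 1) = dgg % (1.0 - square(gg));
      dz.rows(3 * H, 4 * H - 1) = dog % og % (1.0 - og);
      g.Wx[l] += dz * cache.input[t].t();
      g.Wh[l] += dz * cache.h[t].t();
      g.b[l]  += sum(dz, 1);
      dInput[t] = w.Wx[l].t() * dz;
      dh_next = w.Wh[l].t() * dz;
      dc_next = dc % fg;
    }
    if (l > 0) {
      for (int t = 0; t < T; ++t) {
        if (use_drop) {
          const mat& m = caches[l - 1].input[T + t];  // the stored mask
          dH[t] = dInput[t] % m / (1.0 - dropout);
        } else {
          dH[t] = dInput[t];
        }
      }
    }
  }
  return loss;
}

static LstmWeights zeros_like(const LstmWeights& w) {
  LstmWeights g;
  for (size_t l = 0; l < w.Wx.size(); ++l) {
    g.Wx.push_back(mat(size(w.Wx[l]), fill::zeros));
    g.Wh.push_back(mat(size(w.Wh[l]), fill::zeros));
    g.b.push_back(vec(w.b[l].n_elem, fill::zeros));
  }
  g.Wy = mat(size(w.Wy), fill::zeros);
  g.by = vec(w.by.n_elem, fill::zeros);
  return g;
}

// Adam step applied in-place, with shared scalar state t.
struct Adam {
  LstmWeights m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  explicit Adam(const LstmWeights& w) : m(zeros_like(w)), v(zeros_like(w)) {}
  void update_mat(mat& w, mat& mm, mat& vv, const mat& g, double lr) {
    mm = b1 * mm + (1 - b1) * g;
    vv = b2 * vv + (1 - b2) * square(g);
    mat mhat = mm / (1 - std::pow(b1, (double)t));
    mat vhat = vv / (1 - std::pow(b2, (double)t));
    w -= lr * mhat / (sqrt(vhat) + eps);
  }
  void update_vec(vec& w, vec& mm, vec& vv, const vec& g, double lr) {
    mm = b1 * mm + (1 - b1) * g;
    vv = b2 * vv + (1 - b2) * square(g);
    vec mhat = mm / (1 - std::pow(b1, (double)t));
    vec vhat = vv / (1 - std::pow(b2, (double)t));
    w -= lr * mhat / (sqrt(vhat) + eps);
  }
  void step(LstmWeights& w, const LstmWeights& g, double lr) {
    ++t;
    for (size_t l = 0; l < w.Wx.size(); ++l) {
      update_mat(w.Wx[l], m.Wx[l], v.Wx[l], g.Wx[l], lr);
      update_mat(w.Wh[l], m.Wh[l], v.Wh[l], g.Wh[l], lr);
      update_vec(w.b[l], m.b[l], v.b[l], g.b[l], lr);
    }
    update_mat(w.Wy, m.Wy, v.Wy, g.Wy, lr);
    update_vec(w.by, m.by, v.by, g.by, lr);
  }
};

static double eval_loss(const LstmWeights& w, const cube& X, const mat& Y,
                        const uvec& idx, int n_layers, int hidden) {
  if (idx.n_elem == 0) return NA_REAL;
  mat yhat = forward_batch(w, X, idx, n_layers, hidden);
  mat ysub(w.Wy.n_rows, idx.n_elem);
  for (uword b = 0; b < idx.n_elem; ++b) ysub.col(b) = Y.row(idx[b]).t();
  return accu(square(yhat - ysub)) / (double)(ysub.n_elem);
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_train(const arma::cube& X, const arma::mat& Y,
                          int n_layers, int hidden, double dropout,
                          int epochs, int batch_size, double lr, int seed,
                          double val_fraction, int patience) {
  const int N = X.n_slices;
  const int F = X.n_cols;
  const int K = Y.n_cols;
  if ((int)Y.n_rows != N) Rcpp::stop("X and Y example counts differ");
  std::mt19937 rng((unsigned)seed);
  LstmWeights w = init_weights(F, hidden, n_layers, K, rng);
  Adam opt(w);

  // deterministic validation split: shuffle once, last fraction is held out
  std::vector<uword> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  std::shuffle(order.begin(), order.end(), rng);
  int n_val = (int)std::floor(val_fraction * N);
  if (N - n_val < 1) n_val = 0;
  uvec val_idx(n_val), train_idx(N - n_val);
  for (int i = 0; i < N - n_val; ++i) train_idx[i] = order[i];
  for (int i = 0; i < n_val; ++i) val_idx[i] = order[N - n_val + i];

  std::vector<double> train_hist, val_hist;
  double best_val = datum::inf;
  int best_epoch = -1, wait = 0;
  LstmWeights best_w = w;
  int n_train = train_idx.n_elem;
  std::vector<uword> perm(train_idx.begin(), train_idx.end());

  for (int e = 0; e < epochs; ++e) {
    std::shuffle(perm.begin(), perm.end(), rng);
    double ep_loss = 0; long ep_n = 0;
    for (int s = 0; s < n_train; s += batch_size) {
      int bend = std::min(s + batch_size, n_train);
      uvec idx(bend - s);
      for (int i = s; i < bend; ++i) idx[i - s] = perm[i];
      LstmWeights g = zeros_like(w);
      double loss = backward_batch(w, X, Y, idx, n_layers, hidden, dropout,
                                   dropout > 0 ? &rng : nullptr, g);
      if (!std::isfinite(loss))
        Rcpp::stop("training error: non-finite loss at epoch %d", e + 1);
      opt.step(w, g, lr);
      ep_loss += loss * idx.n_elem; ep_n += idx.n_elem;
    }
    train_hist.push_back(ep_loss / ep_n);
    if (n_val > 0) {
      double vl = eval_loss(w, X, Y, val_idx, n_layers, hidden);
      val_hist.push_back(vl);
      if (vl < best_val - 1e-12) {
        best_val = vl; best_epoch = e; best_w = w; wait = 0;
      } else if (++wait >= patience) {
        break;
      }
    }
  }
  if (n_val > 0 && best_epoch >= 0) w = best_w;
  return Rcpp::List::create(
    Rcpp::Named("weights") = weights_to_list(w),
    Rcpp::Named("train_loss") = train_hist,
    Rcpp::Named("val_loss") = val_hist,
    Rcpp::Named("best_epoch") = best_epoch + 1,
    Rcpp::Named("final_train_loss") = train_hist.empty() ? NA_REAL : train_hist.back());
}

// [[Rcpp::export]]
arma::mat cpp_lstm_predict(const Rcpp::List& weights, const arma::cube& X,
                           int n_layers, int hidden) {
  LstmWeights w = list_to_weights(weights, n_layers);
  if ((int)w.Wx[0].n_cols != (int)X.n_cols)
    Rcpp::stop("feature count mismatch: model expects %d, got %d",
               (int)w.Wx[0].n_cols, (int)X.n_cols);
  uvec idx(X.n_slices);
  for (uword i = 0; i < X.n_slices; ++i) idx[i] = i;
  mat yhat = forward_batch(w, X, idx, n_layers, hidden);
  return yhat.t();  // N x K
}

// Loss and exact gradients without dropout, for finite-difference checks.
// [[Rcpp::export]]
Rcpp::List cpp_lstm_grad(const Rcpp::List& weights, const arma::cube& X,
                         const arma::mat& Y, int n_layers, int hidden) {
  LstmWeights w = list_to_weights(weights, n_layers);
  uvec idx(X.n_slices);
  for (uword i = 0; i < X.n_slices; ++i) idx[i] = i;
  LstmWeights g = zeros_like(w);
  double loss = backward_batch(w, X, Y, idx, n_layers, hidden, 0.0, nullptr, g);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = weights_to_list(g));
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_init(int n_features, int hidden, int n_layers,
                         int n_outputs, int seed) {
  std::mt19937 rng((unsigned)seed);
  return weights_to_list(init_weights(n_features, hidden, n_layers, n_outputs, rng));
}

// [[Rcpp::export]]
double cpp_lstm_loss(const Rcpp::List& weights, const arma::cube& X,
                     const arma::mat& Y, int n_layers, int hidden) {
  LstmWeights w = list_to_weights(weights, n_layers);
  uvec idx(X.n_slices);
  for (uword i = 0; i < X.n_slices; ++i) idx[i] = i;
  return eval_loss(w, X, Y, idx, n_layers, hidden);
}
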