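// Recurrent sequence labelers for heart-sound segmentation.
//
// Batched forward / backward-through-time passes and an Adam loop for three
// architectures over scalar feature sequences:
//   gru    : update/reset-gate cell with h_t = (1 - z) .* h~ + z .* h_{t-1}
//   bigru  : forward + backward GRU, states concatenated per step
//   bilstm : forward + backward standard LSTM, states concatenated
// followed by a per-time-step linear layer (shared across steps) and
// softmax cross-entropy over the four cardiac phases.
//
// Gate row layout in the stacked parameter matrices:
//   GRU  W,U,b rows: [update z; reset r; candidate h~]          (3H rows)
//   LSTM W,U,b rows: [input i; forget f; output o; candidate g] (4H rows)
// Input size is fixed at 1 (the envelope feature), so W is (gH x 1).
//
// Canonical parameter order, matching the R side:
//   gru          : W, U, b, Wo, bo
//   bigru/bilstm : Wf, Uf, bf, Wb, Ub, bb, Wo, bo
//
// Performance notes: the output layer (logits, softmax and its gradient) is
// evaluated for all steps at once on an (out x B*T) matrix; the recurrent
// U * h products and the small input projections stay per-step, as the
// recursion demands and cache locality favors.

#include <RcppArmadillo.h>
#ifdef __SSE2__
#include <xmmintrin.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Saturated gates push exp() into the denormal range, where x86 arithmetic
// runs orders of magnitude slower; flush denormals to zero for the duration
// of a call (they are numerically irrelevant here) and restore the FP state
// on exit.
struct FlushDenormals {
#ifdef __SSE2__
  unsigned int saved;
  FlushDenormals() : saved(_mm_getcsr()) { _mm_setcsr(saved | 0x8040); }
  ~FlushDenormals() { _mm_setcsr(saved); }
#endif
};

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// processing step k -> time index t
static inline uword step_time(uword k, uword T, bool rev) {
  return rev ? (T - 1 - k) : k;
}

// ---------------------------------------------------------------- GRU ------

struct GruCache {
  cube z, r, c, h, uhh;  // H x B x T, indexed by processing step
  void init(uword H, uword B, uword T) {
    z.set_size(H, B, T); r.set_size(H, B, T); c.set_size(H, B, T);
    h.set_size(H, B, T); uhh.set_size(H, B, T);
  }
};

static void gru_forward(const mat& W, const mat& U, const vec& b,
                        const mat& X, bool rev, GruCache& cc) {
  const uword T = X.n_rows, B = X.n_cols, H = U.n_cols;
  cc.init(H, B, T);
  mat h(H, B, fill::zeros);
  mat uh(3 * H, B), wx(3 * H, B);
  for (uword k = 0; k < T; ++k) {
    const uword t = step_time(k, T, rev);
    uh = U * h;
    wx = W * X.row(t);
    wx.each_col() += b;
    cc.z.slice(k) = sigm(uh.rows(0, H - 1) + wx.rows(0, H - 1));
    cc.r.slice(k) = sigm(uh.rows(H, 2 * H - 1) + wx.rows(H, 2 * H - 1));
    cc.uhh.slice(k) = uh.rows(2 * H, 3 * H - 1);
    cc.c.slice(k) = tanh(wx.rows(2 * H, 3 * H - 1) +
                         cc.r.slice(k) % cc.uhh.slice(k));
    cc.h.slice(k) = (1.0 - cc.z.slice(k)) % cc.c.slice(k) +
                    cc.z.slice(k) % h;
    h = cc.h.slice(k);
  }
}

// dH: (D x B*T), column block t = gradient wrt the state emitted at time t;
// row_off selects this direction's rows (no copy)
static void gru_backward(const mat& U, const mat& X, bool rev,
                         const GruCache& cc, const mat& dH, uword row_off,
                         mat& dW, mat& dU, mat& db) {
  const uword T = X.n_rows, B = X.n_cols, H = U.n_cols;
  dW.zeros(3 * H, 1);
  dU.zeros(3 * H, H);
  db.zeros(3 * H, 1);
  const mat zerosHB(H, B, fill::zeros);
  mat dh_next(H, B, fill::zeros);
  mat dA_w(3 * H, B), dA_u(3 * H, B);
  for (uword kk = T; kk-- > 0;) {
    const uword t = step_time(kk, T, rev);
    const mat& z = cc.z.slice(kk);
    const mat& r = cc.r.slice(kk);
    const mat& c = cc.c.slice(kk);
    const mat& uhh = cc.uhh.slice(kk);
    const mat& h_prev = (kk == 0) ? zerosHB : cc.h.slice(kk - 1);
    mat dh = dH.submat(row_off, t * B, row_off + H - 1, t * B + B - 1) +
             dh_next;
    mat dc = dh % (1.0 - z);
    mat dac = dc % (1.0 - c % c);
    mat dr = dac % uhh;
    dA_w.rows(0, H - 1) = (dh % (h_prev - c)) % z % (1.0 - z);
    dA_w.rows(H, 2 * H - 1) = dr % r % (1.0 - r);
    dA_w.rows(2 * H, 3 * H - 1) = dac;
    dA_u.rows(0, 2 * H - 1) = dA_w.rows(0, 2 * H - 1);
    dA_u.rows(2 * H, 3 * H - 1) = dac % r;
    dW += dA_w * X.row(t).t();
    db += sum(dA_w, 1);
    dU += dA_u * h_prev.t();
    dh_next = dh % z + U.t() * dA_u;
  }
}

// ---------------------------------------------------------------- LSTM -----

struct LstmCache {
  cube i, f, o, g, cs, tc;  // cs = cell state, tc = tanh(cell state)
  void init(uword H, uword B, uword T) {
    i.set_size(H, B, T); f.set_size(H, B, T); o.set_size(H, B, T);
    g.set_size(H, B, T); cs.set_size(H, B, T); tc.set_size(H, B, T);
  }
};

static void lstm_forward(const mat& W, const mat& U, const vec& b,
                         const mat& X, bool rev, LstmCache& cc) {
  const uword T = X.n_rows, B = X.n_cols, H = U.n_cols;
  cc.init(H, B, T);
  mat h(H, B, fill::zeros), cs(H, B, fill::zeros);
  mat a(4 * H, B);
  for (uword k = 0; k < T; ++k) {
    const uword t = step_time(k, T, rev);
    a = U * h + W * X.row(t);
    a.each_col() += b;
    cc.i.slice(k) = sigm(a.rows(0, H - 1));
    cc.f.slice(k) = sigm(a.rows(H, 2 * H - 1));
    cc.o.slice(k) = sigm(a.rows(2 * H, 3 * H - 1));
    cc.g.slice(k) = tanh(a.rows(3 * H, 4 * H - 1));
    cs = cc.f.slice(k) % cs + cc.i.slice(k) % cc.g.slice(k);
    cc.cs.slice(k) = cs;
    cc.tc.slice(k) = tanh(cs);
    h = cc.o.slice(k) % cc.tc.slice(k);
  }
}

static void lstm_backward(const mat& U, const mat& X, bool rev,
                          const LstmCache& cc, const mat& dH, uword row_off,
                          mat& dW, mat& dU, mat& db) {
  const uword T = X.n_rows, B = X.n_cols, H = U.n_cols;
  dW.zeros(4 * H, 1);
  dU.zeros(4 * H, H);
  db.zeros(4 * H, 1);
  const mat zerosHB(H, B, fill::zeros);
  mat dh_next(H, B, fill::zeros), dc_next(H, B, fill::zeros);
  mat dA(4 * H, B);
  for (uword kk = T; kk-- > 0;) {
    const uword t = step_time(kk, T, rev);
    const mat& i = cc.i.slice(kk);
    const mat& f = cc.f.slice(kk);
    const mat& o = cc.o.slice(kk);
    const mat& g = cc.g.slice(kk);
    const mat& tc = cc.tc.slice(kk);
    const mat& c_prev = (kk == 0) ? zerosHB : cc.cs.slice(kk - 1);
    const mat h_prev = (kk == 0)
        ? zerosHB
        : mat(cc.o.slice(kk - 1) % cc.tc.slice(kk - 1));
    mat dh = dH.submat(row_off, t * B, row_off + H - 1, t * B + B - 1) +
             dh_next;
    mat dc = dc_next + dh % o % (1.0 - tc % tc);
    dA.rows(0, H - 1) = (dc % g) % i % (1.0 - i);
    dA.rows(H, 2 * H - 1) = (dc % c_prev) % f % (1.0 - f);
    dA.rows(2 * H, 3 * H - 1) = (dh % tc) % o % (1.0 - o);
    dA.rows(3 * H, 4 * H - 1) = (dc % i) % (1.0 - g % g);
    dc_next = dc % f;
    dW += dA * X.row(t).t();
    db += sum(dA, 1);
    dU += dA * h_prev.t();
    dh_next = U.t() * dA;
  }
}

// ------------------------------------------------------------ output layer -

enum Arch { A_GRU = 0, A_BIGRU = 1, A_BILSTM = 2 };

static Arch arch_code(const std::string& a) {
  if (a == "gru") return A_GRU;
  if (a == "bigru") return A_BIGRU;
  if (a == "bilstm") return A_BILSTM;
  Rcpp::stop("unknown architecture");
}

// concatenated hidden states for every step: D x (B*T), column block = time
static void collect_states(Arch arch, const GruCache& gf, const GruCache& gb,
                           const LstmCache& lf, const LstmCache& lb,
                           uword T, uword B, mat& out) {
  const bool bi = (arch != A_GRU);
  const bool lstm = (arch == A_BILSTM);
  const uword H = lstm ? lf.i.n_rows : gf.h.n_rows;
  out.set_size(bi ? 2 * H : H, B * T);
  for (uword t = 0; t < T; ++t) {
    if (lstm) {
      out.submat(0, t * B, H - 1, t * B + B - 1) =
          lf.o.slice(t) % lf.tc.slice(t);
      out.submat(H, t * B, 2 * H - 1, t * B + B - 1) =
          lb.o.slice(T - 1 - t) % lb.tc.slice(T - 1 - t);
    } else if (bi) {
      out.submat(0, t * B, H - 1, t * B + B - 1) = gf.h.slice(t);
      out.submat(H, t * B, 2 * H - 1, t * B + B - 1) = gb.h.slice(T - 1 - t);
    } else {
      out.cols(t * B, t * B + B - 1) = gf.h.slice(t);
    }
  }
}

// softmax cross-entropy over all steps at once; Y flattened to B*T with
// column block t = labels at time t
static void softmax_ce_all(const mat& logits, const ivec& y_flat,
                           double scale, double& loss, uword& correct,
                           mat& dlogits, bool want_grad) {
  const uword N = logits.n_cols;
  rowvec mx = max(logits, 0);
  mat E = logits.each_row() - mx;
  E = exp(E);
  rowvec se = sum(E, 0);
  double picked = 0;
  for (uword j = 0; j < N; ++j) {
    const uword cls = (uword)y_flat(j);
    picked += logits(cls, j) - mx(j);
    if ((uword)index_max(logits.col(j)) == cls) ++correct;
  }
  loss += accu(log(se)) - picked;
  if (want_grad) {
    dlogits = E.each_row() / se;
    for (uword j = 0; j < N; ++j) dlogits((uword)y_flat(j), j) -= 1.0;
    dlogits *= scale;
  }
}

// ------------------------------------------------------------- batch pass --

// buffers reused across batches (large allocations happen once per call)
struct Workspace {
  GruCache gf, gb;
  LstmCache lf, lb;
  mat Hcat, logits, dlog, dHall;
};

// one batch: forward, loss + accuracy, optional gradients into G
static void batch_pass(Arch arch, std::vector<mat>& P, const mat& Xb,
                       const imat& Yb, bool want_grad, std::vector<mat>& G,
                       double& loss_sum, uword& correct, Workspace& ws) {
  const uword T = Xb.n_rows, B = Xb.n_cols;
  const double scale = 1.0 / (double)(T * B);
  const bool bi = (arch != A_GRU);
  const bool lstm = (arch == A_BILSTM);
  const mat& Wo = P[P.size() - 2];
  const mat& bo = P[P.size() - 1];
  const uword H = P[1].n_cols;

  if (lstm) {
    lstm_forward(P[0], P[1], P[2].col(0), Xb, false, ws.lf);
    lstm_forward(P[3], P[4], P[5].col(0), Xb, true, ws.lb);
  } else {
    gru_forward(P[0], P[1], P[2].col(0), Xb, false, ws.gf);
    if (bi) gru_forward(P[3], P[4], P[5].col(0), Xb, true, ws.gb);
  }

  collect_states(arch, ws.gf, ws.gb, ws.lf, ws.lb, T, B, ws.Hcat);
  ws.logits = Wo * ws.Hcat;
  ws.logits.each_col() += bo.col(0);

  // flatten labels to match the column blocks of Hcat
  imat yt = Yb.t();  // B x T, so vectorised order is (batch within step)
  ivec y_flat = vectorise(yt);

  softmax_ce_all(ws.logits, y_flat, scale, loss_sum, correct, ws.dlog,
                 want_grad);

  if (want_grad) {
    mat dWo = ws.dlog * ws.Hcat.t();
    mat dbo = sum(ws.dlog, 1);
    ws.dHall = Wo.t() * ws.dlog;  // D x (B*T)
    if (lstm) {
      lstm_backward(P[1], Xb, false, ws.lf, ws.dHall, 0, G[0], G[1], G[2]);
      lstm_backward(P[4], Xb, true, ws.lb, ws.dHall, bi ? H : 0,
                    G[3], G[4], G[5]);
    } else if (bi) {
      gru_backward(P[1], Xb, false, ws.gf, ws.dHall, 0, G[0], G[1], G[2]);
      gru_backward(P[4], Xb, true, ws.gb, ws.dHall, H, G[3], G[4], G[5]);
    } else {
      gru_backward(P[1], Xb, false, ws.gf, ws.dHall, 0, G[0], G[1], G[2]);
    }
    G[G.size() - 2] = dWo;
    G[G.size() - 1] = dbo;
  }
}

// ----------------------------------------------------------------- Adam ----

struct Adam {
  std::vector<mat> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  void init(const std::vector<mat>& params) {
    m.resize(params.size());
    v.resize(params.size());
    for (size_t i = 0; i < params.size(); ++i) {
      m[i].zeros(params[i].n_rows, params[i].n_cols);
      v[i].zeros(params[i].n_rows, params[i].n_cols);
    }
  }
  void update(std::vector<mat>& params, std::vector<mat>& grads,
              double lr, double clip) {
    if (clip > 0) {
      double sq = 0;
      for (const auto& g : grads) sq += accu(square(g));
      const double nrm = std::sqrt(sq);
      if (nrm > clip) {
        const double s = clip / nrm;
        for (auto& g : grads) g *= s;
      }
    }
    ++step;
    const double bc1 = 1.0 - std::pow(b1, (double)step);
    const double bc2 = 1.0 - std::pow(b2, (double)step);
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * grads[i];
      v[i] = b2 * v[i] + (1 - b2) * square(grads[i]);
      params[i] -= lr * (m[i] / bc1) / (sqrt(v[i] / bc2) + eps);
    }
  }
};

// ------------------------------------------------------------- conversions -

static std::vector<std::string> param_names(Arch arch) {
  if (arch == A_GRU) return {"W", "U", "b", "Wo", "bo"};
  return {"Wf", "Uf", "bf", "Wb", "Ub", "bb", "Wo", "bo"};
}

static std::vector<mat> params_from_list(Arch arch, const Rcpp::List& pl) {
  std::vector<mat> P;
  for (const auto& nm : param_names(arch)) {
    P.push_back(Rcpp::as<mat>(pl[nm]));
  }
  return P;
}

static Rcpp::List params_to_list(Arch arch, const std::vector<mat>& P) {
  Rcpp::List out;
  const auto nms = param_names(arch);
  for (size_t i = 0; i < P.size(); ++i) out[nms[i]] = P[i];
  return out;
}

// ------------------------------------------------------------ entry points -

// Train with Adam under per-time-step softmax cross-entropy.
// X: T x N feature windows (columns). Y: T x N labels in 0..C-1.
// order: n_used x epochs matrix of 0-based window indices, one shuffled
// column per epoch (supplied by the caller so runs are seed-reproducible).
// [[Rcpp::export]]
Rcpp::List cpp_rnn_train(std::string arch, Rcpp::List params,
                         const arma::mat& X, const arma::imat& Y,
                         const arma::imat& order, int batch_size,
                         double lr, double clip) {
  FlushDenormals ftz;
  const Arch a = arch_code(arch);
  std::vector<mat> P = params_from_list(a, params);
  std::vector<mat> G(P.size());
  Adam opt;
  opt.init(P);
  const uword T = X.n_rows;
  const uword epochs = order.n_cols, n_used = order.n_rows;
  vec loss_hist(epochs), acc_hist(epochs);
  Workspace ws;
  for (uword ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0;
    uword ep_correct = 0, ep_samples = 0;
    for (uword start = 0; start < n_used; start += (uword)batch_size) {
      const uword stop = std::min(n_used, start + (uword)batch_size);
      const uword B = stop - start;
      mat Xb(T, B);
      imat Yb(T, B);
      for (uword j = 0; j < B; ++j) {
        const uword idx = (uword)order(start + j, ep);
        Xb.col(j) = X.col(idx);
        Yb.col(j) = Y.col(idx);
      }
      double loss_sum = 0;
      uword correct = 0;
      batch_pass(a, P, Xb, Yb, true, G, loss_sum, correct, ws);
      ep_loss += loss_sum;
      ep_correct += correct;
      ep_samples += T * B;
      opt.update(P, G, lr, clip);
      Rcpp::checkUserInterrupt();
    }
    loss_hist(ep) = ep_loss / (double)ep_samples;
    acc_hist(ep) = (double)ep_correct / (double)ep_samples;
  }
  return Rcpp::List::create(
      Rcpp::Named("params") = params_to_list(a, P),
      Rcpp::Named("loss") = loss_hist,
      Rcpp::Named("accuracy") = acc_hist);
}

// Loss and analytic gradients for one batch (used by gradient checks).
// [[Rcpp::export]]
Rcpp::List cpp_rnn_grad(std::string arch, Rcpp::List params,
                        const arma::mat& X, const arma::imat& Y) {
  FlushDenormals ftz;
  const Arch a = arch_code(arch);
  std::vector<mat> P = params_from_list(a, params);
  std::vector<mat> G(P.size());
  double loss_sum = 0;
  uword correct = 0;
  Workspace ws;
  batch_pass(a, P, X, Y, true, G, loss_sum, correct, ws);
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss_sum / (double)(X.n_rows * X.n_cols),
      Rcpp::Named("grads") = params_to_list(a, G));
}

// Mean loss / accuracy without updating parameters.
// [[Rcpp::export]]
Rcpp::List cpp_rnn_evaluate(std::string arch, Rcpp::List params,
                            const arma::mat& X, const arma::imat& Y,
                            int chunk = 16) {
  FlushDenormals ftz;
  const Arch a = arch_code(arch);
  std::vector<mat> P = params_from_list(a, params);
  std::vector<mat> G;
  double loss_sum = 0;
  uword correct = 0;
  const uword N = X.n_cols, T = X.n_rows;
  Workspace ws;
  for (uword start = 0; start < N; start += (uword)chunk) {
    const uword stop = std::min(N, start + (uword)chunk);
    mat Xb = X.cols(start, stop - 1);
    imat Yb = Y.cols(start, stop - 1);
    batch_pass(a, P, Xb, Yb, false, G, loss_sum, correct, ws);
  }
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss_sum / (double)(N * T),
      Rcpp::Named("accuracy") = (double)correct / (double)(N * T));
}

// Per-step class predictions (0-based), ties to the lowest class index.
// [[Rcpp::export]]
arma::imat cpp_rnn_predict(std::string arch, Rcpp::List params,
                           const arma::mat& X, int chunk = 16) {
  FlushDenormals ftz;
  const Arch a = arch_code(arch);
  std::vector<mat> P = params_from_list(a, params);
  const bool bi = (a != A_GRU);
  const bool lstm = (a == A_BILSTM);
  const mat& Wo = P[P.size() - 2];
  const mat& bo = P[P.size() - 1];
  const uword T = X.n_rows, N = X.n_cols;
  imat out(T, N);
  Workspace ws;
  for (uword start = 0; start < N; start += (uword)chunk) {
    const uword stop = std::min(N, start + (uword)chunk);
    mat Xb = X.cols(start, stop - 1);
    const uword B = Xb.n_cols;
    if (lstm) {
      lstm_forward(P[0], P[1], P[2].col(0), Xb, false, ws.lf);
      lstm_forward(P[3], P[4], P[5].col(0), Xb, true, ws.lb);
    } else {
      gru_forward(P[0], P[1], P[2].col(0), Xb, false, ws.gf);
      if (bi) gru_forward(P[3], P[4], P[5].col(0), Xb, true, ws.gb);
    }
    collect_states(a, ws.gf, ws.gb, ws.lf, ws.lb, T, B, ws.Hcat);
    mat logits = Wo * ws.Hcat;
    logits.each_col() += bo.col(0);
    for (uword t = 0; t < T; ++t) {
      for (uword j = 0; j < B; ++j) {
        out(t, start + j) = (sword)index_max(logits.col(t * B + j));
      }
    }
  }
  return out;
}

// Per-step logits for a single window (oracle cross-checks, probabilities).
// [[Rcpp::export]]
arma::mat cpp_rnn_logits(std::string arch, Rcpp::List params,
                         const arma::vec& x) {
  FlushDenormals ftz;
  const Arch a = arch_code(arch);
  std::vector<mat> P = params_from_list(a, params);
  const bool lstm = (a == A_BILSTM);
  const mat& Wo = P[P.size() - 2];
  const mat& bo = P[P.size() - 1];
  const uword T = x.n_elem;
  mat Xb(x);
  Workspace ws;
  if (lstm) {
    lstm_forward(P[0], P[1], P[2].col(0), Xb, false, ws.lf);
    lstm_forward(P[3], P[4], P[5].col(0), Xb, true, ws.lb);
  } else {
    gru_forward(P[0], P[1], P[2].col(0), Xb, false, ws.gf);
    if (a != A_GRU) gru_forward(P[3], P[4], P[5].col(0), Xb, true, ws.gb);
  }
  collect_states(a, ws.gf, ws.gb, ws.lf, ws.lb, T, 1, ws.Hcat);
  mat logits = Wo * ws.Hcat;  // C x T
  logits.each_col() += bo.col(0);
  return logits.t();
}
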