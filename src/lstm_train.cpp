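// Training loop for the stacked gate-equation LSTM + linear read-out.
// Mirrors the R-level forward pass exactly (gate order f, i, c, o on the
// concatenated [h_prev, x] vector); gradients by backpropagation through
// time on the squared one-step-ahead error, per-sample updates.
// All randomness (init, sample order) is drawn in R and passed in, so
// results are reproducible and independent of the C RNG.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline vec sigmoid_vec(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

struct AdamState {
  mat mW, vW;
  vec mb, vb;
};

static inline void adam_update(mat& W, vec& b, const mat& gW, const vec& gb,
                               AdamState& st, double lr, double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  st.mW = b1 * st.mW + (1 - b1) * gW;
  st.vW = b2 * st.vW + (1 - b2) * square(gW);
  st.mb = b1 * st.mb + (1 - b1) * gb;
  st.vb = b2 * st.vb + (1 - b2) * square(gb);
  double c1 = 1 - std::pow(b1, t), c2 = 1 - std::pow(b2, t);
  W -= lr * (st.mW / c1) / (sqrt(st.vW / c2) + eps);
  b -= lr * (st.mb / c1) / (sqrt(st.vb / c2) + eps);
}

// [[Rcpp::export(name = ".lstm_train_cpp")]]
Rcpp::List lstm_train_cpp(const arma::mat& X,      // n x T windows
                          const arma::vec& y,      // n targets
                          Rcpp::List layers0,      // per layer: W (4H x (H+in)), b (4H)
                          const arma::vec& w_out0,
                          const arma::vec& w_skip0, double b_out0,
                          const arma::imat& order, // epochs x n sample order (1-based)
                          double lr0, double decay,
                          const std::string& optimizer) {
  const int T = X.n_cols;
  const int L = layers0.size();
  const int epochs = order.n_rows;
  const int ntr = order.n_cols;
  const bool adam = optimizer == "adam";

  std::vector<mat> W(L);
  std::vector<vec> b(L);
  for (int l = 0; l < L; ++l) {
    Rcpp::List lay = layers0[l];
    W[l] = Rcpp::as<mat>(lay["W"]);
    b[l] = Rcpp::as<vec>(lay["b"]);
  }
  const int H = W[0].n_rows / 4;
  vec w_out = w_out0;
  vec w_skip = w_skip0;
  double b_out = b_out0;

  std::vector<AdamState> st(L);
  for (int l = 0; l < L; ++l) {
    st[l].mW = zeros<mat>(size(W[l])); st[l].vW = zeros<mat>(size(W[l]));
    st[l].mb = zeros<vec>(4 * H);      st[l].vb = zeros<vec>(4 * H);
  }
  vec m_wout = zeros<vec>(H), v_wout = zeros<vec>(H);
  vec m_skip = zeros<vec>(1), v_skip = zeros<vec>(1);
  double m_bout = 0, v_bout = 0, step = 0;

  // caches per layer: columns are timesteps
  std::vector<mat> Zc(L), Fc(L), Ic(L), Cb(L), Oc(L), Cp(L), Cc(L), Tc(L);
  for (int l = 0; l < L; ++l) {
    int in = W[l].n_cols - H;
    Zc[l] = zeros<mat>(H + in, T);
    Fc[l] = Ic[l] = Cb[l] = Oc[l] = Cp[l] = Cc[l] = Tc[l] = zeros<mat>(H, T);
  }

  vec loss_hist(epochs, fill::zeros);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  for (int e = 0; e < epochs; ++e) {
    double lr = lr0 * std::pow(decay, e);
    double acc = 0;
    for (int s = 0; s < ntr; ++s) {
      int idx = order(e, s) - 1;

      // ---- forward ----
      vec h_low;                      // hidden sequence output of top layer
      for (int l = 0; l < L; ++l) {
        vec h = zeros<vec>(H), c = zeros<vec>(H);
        int in = W[l].n_cols - H;
        for (int t = 0; t < T; ++t) {
          vec z(H + in);
          z.head(H) = h;
          if (l == 0) z(H) = X(idx, t);
          else        z.tail(in) = Tc[l - 1].col(t) % Oc[l - 1].col(t); // h below
          vec a = W[l] * z + b[l];
          vec f = sigmoid_vec(a.subvec(0, H - 1));
          vec i = sigmoid_vec(a.subvec(H, 2 * H - 1));
          vec cb = tanh(a.subvec(2 * H, 3 * H - 1));
          vec o = sigmoid_vec(a.subvec(3 * H, 4 * H - 1));
          Cp[l].col(t) = c;
          c = f % c + i % cb;
          vec tc = tanh(c);
          h = o % tc;
          Zc[l].col(t) = z; Fc[l].col(t) = f; Ic[l].col(t) = i;
          Cb[l].col(t) = cb; Oc[l].col(t) = o; Cc[l].col(t) = c;
          Tc[l].col(t) = tc;
        }
        h_low = h;
      }
      double yhat = dot(h_low, w_out) + X(idx, T - 1) * w_skip(0) + b_out;
      double err = yhat - y(idx);
      acc += err * err;

      // ---- backward ----
      double dy = 2 * err;
      vec g_wout = dy * (Tc[L - 1].col(T - 1) % Oc[L - 1].col(T - 1));
      vec g_skip(1); g_skip(0) = dy * X(idx, T - 1);
      double g_bout = dy;

      mat dh_ext = zeros<mat>(H, T);       // external dh into current layer
      dh_ext.col(T - 1) = dy * w_out;

      std::vector<mat> gW(L);
      std::vector<vec> gb(L);
      for (int l = L - 1; l >= 0; --l) {
        int in = W[l].n_cols - H;
        gW[l] = zeros<mat>(size(W[l]));
        gb[l] = zeros<vec>(4 * H);
        vec dh_next = zeros<vec>(H), dc_next = zeros<vec>(H);
        mat dx_out = zeros<mat>(in, T);
        for (int t = T - 1; t >= 0; --t) {
          vec dh = dh_ext.col(t) + dh_next;
          vec f = Fc[l].col(t), i = Ic[l].col(t), cb = Cb[l].col(t),
              o = Oc[l].col(t), tc = Tc[l].col(t);
          vec do_ = dh % tc;
          vec dc = dh % o % (1 - square(tc)) + dc_next;
          vec df = dc % Cp[l].col(t);
          vec di = dc % cb;
          vec dcb = dc % i;
          dc_next = dc % f;
          vec dz_gate(4 * H);
          dz_gate.subvec(0, H - 1) = df % f % (1 - f);
          dz_gate.subvec(H, 2 * H - 1) = di % i % (1 - i);
          dz_gate.subvec(2 * H, 3 * H - 1) = dcb % (1 - square(cb));
          dz_gate.subvec(3 * H, 4 * H - 1) = do_ % o % (1 - o);
          gW[l] += dz_gate * Zc[l].col(t).t();
          gb[l] += dz_gate;
          vec dz_in = W[l].t() * dz_gate;
          dh_next = dz_in.head(H);
          dx_out.col(t) = dz_in.tail(in);
        }
        if (l > 0) dh_ext = dx_out;   // flows into h of the layer below
      }

      // ---- update ----
      step += 1;
      if (adam) {
        for (int l = 0; l < L; ++l) {
          adam_update(W[l], b[l], gW[l], gb[l], st[l], lr, step);
        }
        m_wout = b1 * m_wout + (1 - b1) * g_wout;
        v_wout = b2 * v_wout + (1 - b2) * square(g_wout);
        double c1 = 1 - std::pow(b1, step), c2 = 1 - std::pow(b2, step);
        w_out -= lr * (m_wout / c1) / (sqrt(v_wout / c2) + eps);
        m_skip = b1 * m_skip + (1 - b1) * g_skip;
        v_skip = b2 * v_skip + (1 - b2) * square(g_skip);
        w_skip -= lr * (m_skip / c1) / (sqrt(v_skip / c2) + eps);
        m_bout = b1 * m_bout + (1 - b1) * g_bout;
        v_bout = b2 * v_bout + (1 - b2) * g_bout * g_bout;
        b_out -= lr * (m_bout / c1) / (std::sqrt(v_bout / c2) + eps);
      } else {
        for (int l = 0; l < L; ++l) {
          W[l] -= lr * gW[l];
          b[l] -= lr * gb[l];
        }
        w_out -= lr * g_wout;
        w_skip -= lr * g_skip;
        b_out -= lr * g_bout;
      }
    }
    loss_hist(e) = acc / ntr;
    if (!std::isfinite(loss_hist(e))) {
      Rcpp::stop("training diverged (non-finite loss) at epoch %d", e + 1);
    }
    if (e % 50 == 0) Rcpp::checkUserInterrupt();
  }

  Rcpp::List out_layers(L);
  for (int l = 0; l < L; ++l) {
    out_layers[l] = Rcpp::List::create(Rcpp::Named("W") = W[l],
                                       Rcpp::Named("b") = b[l]);
  }
  return Rcpp::List::create(
    Rcpp::Named("layers") = out_layers,
    Rcpp::Named("w_out") = w_out,
    Rcpp::Named("w_skip") = w_skip,
    Rcpp::Named("b_out") = b_out,
    Rcpp::Named("loss") = loss_hist);
}
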