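// Hot path of network training: per-model forward/backward/Adam steps.
// Mirrors the R-level forward pass exactly; the R side owns initialization,
// shuffling, and all user-facing behavior.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::as;

namespace {

struct Layer {
  fmat W;
  frowvec b;
  fmat mW, vW;
  frowvec mb, vb;
  bool used = false;
};

inline fmat affine(const fmat& X, const Layer& L) {
  fmat Y = X * L.W;
  Y.each_row() += L.b;
  return Y;
}

inline void relu_ip(fmat& X) { X.clamp(0.0f, fdatum::inf); }

struct Grad {
  fmat W;
  frowvec b;
};

inline Grad layer_grad(const fmat& X, const fmat& dZ) {
  return Grad{X.t() * dZ, sum(dZ, 0)};
}

// dZ for a relu layer with post-activation A and upstream gradient dA.
inline fmat relu_back(const fmat& dA, const fmat& A) {
  return dA % conv_to<fmat>::from(A > 0.0f);
}

void adam_update(Layer& L, const Grad& g, float lr, float b1, float b2,
                 float eps, float corr1, float corr2) {
  L.mW = b1 * L.mW + (1 - b1) * g.W;
  L.vW = b2 * L.vW + (1 - b2) * square(g.W);
  L.mb = b1 * L.mb + (1 - b1) * g.b;
  L.vb = b2 * L.vb + (1 - b2) * square(g.b);
  L.W -= lr * (L.mW / corr1) / (sqrt(L.vW / corr2) + eps);
  L.b -= lr * (L.mb / corr1) / (sqrt(L.vb / corr2) + eps);
}

Layer read_layer(const List& l) {
  Layer L;
  L.W = conv_to<fmat>::from(as<mat>(l["W"]));
  L.b = conv_to<frowvec>::from(as<vec>(l["b"]).t());
  L.mW = zeros<fmat>(L.W.n_rows, L.W.n_cols);
  L.vW = L.mW;
  L.mb = zeros<frowvec>(L.b.n_elem);
  L.vb = L.mb;
  L.used = true;
  return L;
}

List write_layer(const Layer& L) {
  return List::create(Rcpp::Named("W") = conv_to<mat>::from(L.W),
                      Rcpp::Named("b") = conv_to<vec>::from(conv_to<rowvec>::from(L.b)));
}

} // namespace

// [[Rcpp::export(name = ".cf_train_cpp")]]
List cf_train_cpp(List weights, List samples, List cfg, Rcpp::IntegerMatrix orders) {
  const bool shared = as<bool>(cfg["share_weights"]);
  const bool single = as<bool>(cfg["single_channel"]);
  const float lr = float(as<double>(cfg["learning_rate"]));
  const float b1 = float(as<double>(cfg["beta1"]));
  const float b2 = float(as<double>(cfg["beta2"]));
  const float eps = float(as<double>(cfg["adam_eps"]));

  Layer trunk1 = read_layer(weights["trunk1"]);
  Layer trunk2 = read_layer(weights["trunk2"]);
  Layer trunk1q, trunk2q;
  const bool has_qtrunk = !shared && !single;
  if (has_qtrunk) {
    trunk1q = read_layer(weights["trunk1q"]);
    trunk2q = read_layer(weights["trunk2q"]);
  }
  Layer fc3 = read_layer(weights["fc3"]);
  Layer fc4 = read_layer(weights["fc4"]);
  Layer fc5 = read_layer(weights["fc5"]);
  Layer fc6 = read_layer(weights["fc6"]);
  const uword k3 = fc3.W.n_cols;

  const int n_samples = samples.size();
  std::vector<fmat> Ss(n_samples), Qs(n_samples), Ts(n_samples);
  for (int i = 0; i < n_samples; ++i) {
    List s = samples[i];
    if (!single) Ss[i] = conv_to<fmat>::from(as<mat>(s["S"]));
    Qs[i] = conv_to<fmat>::from(as<mat>(s["Q"]));
    Ts[i] = conv_to<fmat>::from(as<mat>(s["T"]));
  }

  const int epochs = orders.nrow();
  vec loss_history(epochs, fill::zeros);
  long t = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0;
    for (int j = 0; j < orders.ncol(); ++j) {
      const int i = orders(ep, j) - 1;
      const fmat& Q = Qs[i];
      const fmat& T = Ts[i];

      const Layer& tq1 = has_qtrunk ? trunk1q : trunk1;
      const Layer& tq2 = has_qtrunk ? trunk2q : trunk2;
      fmat A1q = affine(Q, tq1); relu_ip(A1q);
      fmat A2q = affine(A1q, tq2); relu_ip(A2q);

      fmat A1s, A2s;
      const fmat* Sin = nullptr;
      const fmat* A2s_p = nullptr;
      if (single) {
        Sin = &Q; A2s_p = &A2q;
      } else {
        Sin = &Ss[i];
        A1s = affine(*Sin, trunk1); relu_ip(A1s);
        A2s = affine(A1s, trunk2); relu_ip(A2s);
        A2s_p = &A2s;
      }

      fmat H = affine(*A2s_p, fc3); relu_ip(H);
      uvec imax(k3);
      frowvec g(k3);
      for (uword c = 0; c < k3; ++c) {
        imax(c) = H.col(c).index_max();
        g(c) = H(imax(c), c);
      }

      fmat L = affine(A2q, fc4); relu_ip(L);
      fmat Z(Q.n_rows, k3 + L.n_cols);
      Z.cols(0, k3 - 1) = repmat(g, Q.n_rows, 1);
      Z.cols(k3, Z.n_cols - 1) = L;
      fmat A5 = affine(Z, fc5); relu_ip(A5);
      fmat out = affine(A5, fc6);

      fmat err = out - T;
      ep_loss += double(accu(abs(err))) / err.n_elem;
      fmat dOut = sign(err) / float(err.n_elem);

      Grad g6 = layer_grad(A5, dOut);
      fmat dA5 = dOut * fc6.W.t();
      fmat dZ5 = relu_back(dA5, A5);
      Grad g5 = layer_grad(Z, dZ5);
      fmat dZ = dZ5 * fc5.W.t();
      frowvec dG = sum(dZ.cols(0, k3 - 1), 0);
      fmat dL = dZ.cols(k3, dZ.n_cols - 1);

      fmat dH(H.n_rows, H.n_cols, fill::zeros);
      for (uword c = 0; c < k3; ++c) {
        if (H(imax(c), c) > 0.0f) dH(imax(c), c) = dG(c);
      }
      // relu mask already applied above (gradient only where H > 0)
      Grad g3 = layer_grad(*A2s_p, dH);
      fmat dA2s = dH * fc3.W.t();

      fmat dZ4 = relu_back(dL, L);
      Grad g4 = layer_grad(A2q, dZ4);
      fmat dA2q = dZ4 * fc4.W.t();

      auto trunk_back = [&](const fmat& dA2, const fmat& A2, const fmat& A1,
                            const fmat& X, const Layer& l2, Grad& g1, Grad& g2) {
        fmat dZ2 = relu_back(dA2, A2);
        g2 = layer_grad(A1, dZ2);
        fmat dA1 = dZ2 * l2.W.t();
        fmat dZ1 = relu_back(dA1, A1);
        g1 = layer_grad(X, dZ1);
      };

      Grad g1, g2;
      Grad g1q, g2q;
      bool have_q = false;
      if (single) {
        fmat dA2 = dA2s + dA2q;
        trunk_back(dA2, A2q, A1q, Q, trunk2, g1, g2);
      } else if (shared) {
        trunk_back(dA2s, A2s, A1s, *Sin, trunk2, g1, g2);
        trunk_back(dA2q, A2q, A1q, Q, trunk2, g1q, g2q);
        g1.W += g1q.W; g1.b += g1q.b;
        g2.W += g2q.W; g2.b += g2q.b;
      } else {
        trunk_back(dA2s, A2s, A1s, *Sin, trunk2, g1, g2);
        trunk_back(dA2q, A2q, A1q, Q, trunk2q, g1q, g2q);
        have_q = true;
      }

      ++t;
      const float corr1 = 1.0f - float(std::pow(double(b1), double(t)));
      const float corr2 = 1.0f - float(std::pow(double(b2), double(t)));
      adam_update(trunk1, g1, lr, b1, b2, eps, corr1, corr2);
      adam_update(trunk2, g2, lr, b1, b2, eps, corr1, corr2);
      if (have_q) {
        adam_update(trunk1q, g1q, lr, b1, b2, eps, corr1, corr2);
        adam_update(trunk2q, g2q, lr, b1, b2, eps, corr1, corr2);
      }
      adam_update(fc3, g3, lr, b1, b2, eps, corr1, corr2);
      adam_update(fc4, g4, lr, b1, b2, eps, corr1, corr2);
      adam_update(fc5, g5, lr, b1, b2, eps, corr1, corr2);
      adam_update(fc6, g6, lr, b1, b2, eps, corr1, corr2);
    }
    loss_history(ep) = ep_loss / orders.ncol();
  }

  List w_out = List::create(
    Rcpp::Named("trunk1") = write_layer(trunk1),
    Rcpp::Named("trunk2") = write_layer(trunk2),
    Rcpp::Named("fc3") = write_layer(fc3),
    Rcpp::Named("fc4") = write_layer(fc4),
    Rcpp::Named("fc5") = write_layer(fc5),
    Rcpp::Named("fc6") = write_layer(fc6)
  );
  if (has_qtrunk) {
    w_out["trunk1q"] = write_layer(trunk1q);
    w_out["trunk2q"] = write_layer(trunk2q);
  }
  return List::create(
    Rcpp::Named("weights") = w_out,
    Rcpp::Named("loss_history") = loss_history,
    Rcpp::Named("step") = double(t)
  );
}
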