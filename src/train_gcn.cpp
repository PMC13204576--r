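// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Fast training engine for the Chebyshev GCN. Mirrors the R reference
// implementation (layers.R / fit.R) operation for operation: channel-major
// features (C x N), per-graph batch normalization, Leaky ReLU, optional
// second batchnorm, dropout on the final features, softmax + weighted
// cross-entropy, Adadelta updates with weight decay on the convolution
// coefficients only. The two engines are asserted equal in the test suite
// (shuffle and dropout disabled, where no RNG is consumed).

namespace {

constexpr double BN_EPS = 1e-5;

struct BN {
  arma::vec gamma, beta, run_mean, run_var;
  // caches
  arma::mat xhat;
  arma::vec istd;
  bool identity = false;
};

struct Block {
  std::vector<arma::mat> theta;   // din x dout
  arma::vec bias;                 // dout
  BN bn1, bn2;
  bool has_bn2;
  // caches
  std::vector<arma::mat> S;       // basis signals, din x N
  arma::mat pre_act;              // bn1 output
};

struct AdaState {
  arma::mat Eg2, Edx;
};

void bn_forward(BN& bn, arma::mat& X, bool train, double momentum) {
  const arma::uword n = X.n_cols;
  if (train) {
    if (n < 2) { bn.identity = true; return; }
    bn.identity = false;
    arma::vec mu = arma::mean(X, 1);
    X.each_col() -= mu;
    arma::vec v = arma::mean(arma::square(X), 1);
    bn.istd = 1.0 / arma::sqrt(v + BN_EPS);
    X.each_col() %= bn.istd;
    bn.xhat = X;
    X.each_col() %= bn.gamma;
    X.each_col() += bn.beta;
    bn.run_mean = (1 - momentum) * bn.run_mean + momentum * mu;
    double unb = (double) n / std::max((double) n - 1.0, 1.0);
    bn.run_var = (1 - momentum) * bn.run_var + momentum * v * unb;
  } else {
    arma::vec istd = 1.0 / arma::sqrt(bn.run_var + BN_EPS);
    X.each_col() -= bn.run_mean;
    X.each_col() %= istd % bn.gamma;
    X.each_col() += bn.beta;
  }
}

// returns dX; fills dgamma/dbeta
arma::mat bn_backward(const BN& bn, const arma::mat& dOut,
                      arma::vec& dgamma, arma::vec& dbeta) {
  if (bn.identity) {
    dgamma.zeros(bn.gamma.n_elem);
    dbeta.zeros(bn.beta.n_elem);
    return dOut;
  }
  dgamma = arma::sum(dOut % bn.xhat, 1);
  dbeta = arma::sum(dOut, 1);
  arma::mat dxhat = dOut;
  dxhat.each_col() %= bn.gamma;
  arma::mat term = dxhat;
  term.each_col() -= arma::mean(dxhat, 1);
  arma::vec c = arma::mean(dxhat % bn.xhat, 1);
  term -= bn.xhat.each_col() % c;
  term.each_col() %= bn.istd;
  return term;
}

void adadelta_update(arma::mat& par, const arma::mat& g, AdaState& st,
                     double lr, double rho, double eps) {
  st.Eg2 = rho * st.Eg2 + (1 - rho) * (g % g);
  arma::mat dx = arma::sqrt((st.Edx + eps) / (st.Eg2 + eps)) % g;
  st.Edx = rho * st.Edx + (1 - rho) * (dx % dx);
  par -= lr * dx;
}

}  // namespace

// [[Rcpp::export]]
List train_gcn_cpp(List lts, List xts, List ys, List params_in,
                   IntegerMatrix orders_by_epoch,  // epochs x n_graphs, 1-based
                   double leaky_slope, double dropout_rate,
                   double lr, double rho, double eps, double weight_decay,
                   double bn_momentum, NumericVector class_w) {
  const int ng = lts.size();
  const int epochs = orders_by_epoch.nrow();

  std::vector<arma::mat> Lt(ng), Xt(ng);
  std::vector<arma::ivec> Y(ng);
  for (int i = 0; i < ng; ++i) {
    Lt[i] = as<arma::mat>(lts[i]);
    Xt[i] = as<arma::mat>(xts[i]);
    Y[i] = as<arma::ivec>(ys[i]);
  }

  const int nb = params_in.size();
  std::vector<Block> blocks(nb);
  std::vector<std::vector<AdaState>> st_theta(nb);
  std::vector<AdaState> st_bias(nb), st_g1(nb), st_b1(nb), st_g2(nb), st_b2(nb);
  for (int b = 0; b < nb; ++b) {
    List pb = params_in[b];
    List th = pb["theta"];
    Block& B = blocks[b];
    for (int k = 0; k < th.size(); ++k) {
      B.theta.push_back(as<arma::mat>(th[k]));
      AdaState s; s.Eg2.zeros(B.theta[k].n_rows, B.theta[k].n_cols);
      s.Edx = s.Eg2;
      st_theta[b].push_back(s);
    }
    B.bias = as<arma::vec>(pb["bias"]);
    List bn1 = pb["bn1"];
    B.bn1.gamma = as<arma::vec>(bn1["gamma"]);
    B.bn1.beta = as<arma::vec>(bn1["beta"]);
    B.bn1.run_mean = as<arma::vec>(bn1["run_mean"]);
    B.bn1.run_var = as<arma::vec>(bn1["run_var"]);
    B.has_bn2 = !Rf_isNull(pb["bn2"]);
    if (B.has_bn2) {
      List bn2 = pb["bn2"];
      B.bn2.gamma = as<arma::vec>(bn2["gamma"]);
      B.bn2.beta = as<arma::vec>(bn2["beta"]);
      B.bn2.run_mean = as<arma::vec>(bn2["run_mean"]);
      B.bn2.run_var = as<arma::vec>(bn2["run_var"]);
    }
    const arma::uword dout = B.bias.n_elem;
    AdaState sv; sv.Eg2.zeros(dout, 1); sv.Edx = sv.Eg2;
    st_bias[b] = sv; st_g1[b] = sv; st_b1[b] = sv;
    if (B.has_bn2) { st_g2[b] = sv; st_b2[b] = sv; }
  }

  const double keep = 1 - dropout_rate;
  NumericVector loss_hist(epochs);
  RNGScope rng;  // dropout consumes the R RNG stream

  std::vector<arma::mat> act_grad(nb);

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0;
    for (int oi = 0; oi < ng; ++oi) {
      const int gi = orders_by_epoch(ep, oi) - 1;
      const arma::mat& L = Lt[gi];
      const arma::ivec& y = Y[gi];
      const arma::uword N = Xt[gi].n_cols;

      // ---- forward ----
      arma::mat H = Xt[gi];
      for (int b = 0; b < nb; ++b) {
        Block& B = blocks[b];
        const int O = B.theta.size();
        B.S.assign(O, arma::mat());
        B.S[0] = H;
        if (O >= 2) B.S[1] = B.S[0] * L;
        for (int k = 2; k < O; ++k) B.S[k] = 2 * (B.S[k - 1] * L) - B.S[k - 2];
        arma::mat out = B.theta[0].t() * B.S[0];
        for (int k = 1; k < O; ++k) out += B.theta[k].t() * B.S[k];
        out.each_col() += B.bias;
        bn_forward(B.bn1, out, true, bn_momentum);
        B.pre_act = out;
        arma::mat g = arma::conv_to<arma::mat>::from(out >= 0.0);
        g = g + leaky_slope * (1.0 - g);
        act_grad[b] = g;
        out %= g;
        if (B.has_bn2) bn_forward(B.bn2, out, true, bn_momentum);
        H = out;
      }
      arma::mat drop_mask;
      if (dropout_rate > 0) {
        drop_mask.set_size(H.n_rows, H.n_cols);
        for (arma::uword j = 0; j < drop_mask.n_elem; ++j)
          drop_mask[j] = (unif_rand() < keep) ? 1.0 / keep : 0.0;
        H %= drop_mask;
      }
      // softmax + weighted cross-entropy
      arma::rowvec m = arma::max(H, 0);
      arma::mat E = arma::exp(H.each_row() - m);
      arma::rowvec s = arma::sum(E, 0);
      arma::mat P = E.each_row() / s;
      double sw = 0, loss = 0;
      arma::rowvec w(N);
      for (arma::uword i = 0; i < N; ++i) {
        w[i] = class_w[y[i]];
        sw += w[i];
        double py = P(y[i], i);
        loss -= w[i] * std::log(std::max(py, 1e-12));
      }
      loss /= sw;
      ep_loss += loss;

      // ---- backward ----
      arma::mat dH = P;
      for (arma::uword i = 0; i < N; ++i) dH(y[i], i) -= 1.0;
      dH.each_row() %= (w / sw);
      if (dropout_rate > 0) dH %= drop_mask;

      for (int b = nb - 1; b >= 0; --b) {
        Block& B = blocks[b];
        const int O = B.theta.size();
        arma::vec dg2, db2, dg1, db1;
        if (B.has_bn2) dH = bn_backward(B.bn2, dH, dg2, db2);
        dH %= act_grad[b];
        dH = bn_backward(B.bn1, dH, dg1, db1);
        // convolution gradients
        std::vector<arma::mat> dtheta(O);
        for (int k = 0; k < O; ++k) dtheta[k] = B.S[k] * dH.t();
        arma::vec dbias = arma::sum(dH, 1);
        arma::mat dX = B.theta[0] * dH;
        if (O >= 2) dX += (B.theta[1] * dH) * L;
        for (int k = 2; k < O; ++k) {
          arma::mat V = B.theta[k] * dH;
          arma::mat t0 = V, t1 = V * L;
          for (int j = 2; j <= k; ++j) {  // T_k needs k-1 recurrence steps
            arma::mat t2 = 2 * (t1 * L) - t0;
            t0 = t1; t1 = t2;
          }
          dX += t1;
        }
        // ---- Adadelta updates ----
        for (int k = 0; k < O; ++k) {
          arma::mat g = dtheta[k] + weight_decay * B.theta[k];
          adadelta_update(B.theta[k], g, st_theta[b][k], lr, rho, eps);
        }
        {
          arma::mat par(B.bias), g(dbias);
          adadelta_update(par, g, st_bias[b], lr, rho, eps);
          B.bias = par.col(0);
        }
        {
          arma::mat par(B.bn1.gamma), g(dg1);
          adadelta_update(par, g, st_g1[b], lr, rho, eps);
          B.bn1.gamma = par.col(0);
          arma::mat par2(B.bn1.beta), g2(db1);
          adadelta_update(par2, g2, st_b1[b], lr, rho, eps);
          B.bn1.beta = par2.col(0);
        }
        if (B.has_bn2) {
          arma::mat par(B.bn2.gamma), g(dg2);
          adadelta_update(par, g, st_g2[b], lr, rho, eps);
          B.bn2.gamma = par.col(0);
          arma::mat par2(B.bn2.beta), g2(db2);
          adadelta_update(par2, g2, st_b2[b], lr, rho, eps);
          B.bn2.beta = par2.col(0);
        }
        dH = dX;
      }
    }
    loss_hist[ep] = ep_loss / ng;
  }

  // repack parameters
  List params_out(nb);
  for (int b = 0; b < nb; ++b) {
    Block& B = blocks[b];
    List th(B.theta.size());
    for (size_t k = 0; k < B.theta.size(); ++k) th[k] = wrap(B.theta[k]);
    List bn1 = List::create(
      _["gamma"] = NumericVector(B.bn1.gamma.begin(), B.bn1.gamma.end()),
      _["beta"] = NumericVector(B.bn1.beta.begin(), B.bn1.beta.end()),
      _["run_mean"] = NumericVector(B.bn1.run_mean.begin(), B.bn1.run_mean.end()),
      _["run_var"] = NumericVector(B.bn1.run_var.begin(), B.bn1.run_var.end()));
    List pb = params_in[b];
    List out = List::create(
      _["theta"] = th, _["bias"] = NumericVector(B.bias.begin(), B.bias.end()),
      _["bn1"] = bn1,
      _["bn2"] = R_NilValue,
      _["order"] = pb["order"], _["din"] = pb["din"], _["dout"] = pb["dout"]);
    if (B.has_bn2) {
      out["bn2"] = List::create(
        _["gamma"] = NumericVector(B.bn2.gamma.begin(), B.bn2.gamma.end()),
        _["beta"] = NumericVector(B.bn2.beta.begin(), B.bn2.beta.end()),
        _["run_mean"] = NumericVector(B.bn2.run_mean.begin(), B.bn2.run_mean.end()),
        _["run_var"] = NumericVector(B.bn2.run_var.begin(), B.bn2.run_var.end()));
    }
    params_out[b] = out;
  }
  return List::create(_["params"] = params_out, _["loss_history"] = loss_hist);
}
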