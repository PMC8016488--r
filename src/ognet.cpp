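// Network kernels: embedding + SELU convolution + masked adaptive max-pooling
// (ognet variant) and fixed-length one-hot + batch-norm ReLU convolution +
// 1-max pooling + hidden layer (deepfam variant). Forward and exact backward
// passes; optimization itself (Adam) lives in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double SELU_LAMBDA = 1.0507009873554804934193349852946;
static const double SELU_ALPHA  = 1.6732632423543772848170429916717;

static inline double selu(double x) {
  return x > 0 ? SELU_LAMBDA * x : SELU_LAMBDA * SELU_ALPHA * (std::exp(x) - 1.0);
}
static inline double selu_grad(double x) {
  return x > 0 ? SELU_LAMBDA : SELU_LAMBDA * SELU_ALPHA * std::exp(x);
}

// mean cross-entropy of labels (0-based) under logits; also writes softmax
// gradient dlogits = (p - onehot)/B into g
static double xent_and_grad(const arma::mat& logits, const IntegerVector& labels,
                            arma::mat& g) {
  const arma::uword B = logits.n_rows;
  g = logits;
  double loss = 0.0;
  for (arma::uword b = 0; b < B; ++b) {
    double m = logits.row(b).max();
    arma::rowvec e = arma::exp(logits.row(b) - m);
    double s = arma::accu(e);
    loss += std::log(s) + m - logits(b, labels[b]);
    g.row(b) = e / s;
    g(b, labels[b]) -= 1.0;
  }
  g /= (double)B;
  return loss / (double)B;
}

struct OgWeights {
  arma::mat E;                  // (A+1) x D, row 0 = padding (all zero)
  std::vector<arma::mat> Wk;    // (K*D) x F, row index j*D + d
  std::vector<arma::vec> bk;    // F
  arma::mat Wout;               // (nK*F) x C
  arma::rowvec bout;            // C
};

static OgWeights unpack_ognet(const List& w, const IntegerVector& ks) {
  OgWeights out;
  out.E = as<arma::mat>(w["embedding"]);
  for (int i = 0; i < ks.size(); ++i) {
    std::string k = std::to_string(ks[i]);
    out.Wk.push_back(as<arma::mat>(w["conv_w_" + k]));
    out.bk.push_back(as<arma::vec>(w["conv_b_" + k]));
  }
  out.Wout = as<arma::mat>(w["out_w"]);
  out.bout = as<arma::rowvec>(w["out_b"]);
  return out;
}

// Embed one padded row of the batch into Xt (D x Luse); index 0 is the
// padding row of E (kept at zero), so padded positions embed to zero.
static void embed_seq(const OgWeights& W, const IntegerMatrix& batch, int b,
                      int Luse, arma::mat& Xt) {
  const int D = W.E.n_cols;
  const int A1 = W.E.n_rows;
  Xt.set_size(D, Luse);
  for (int t = 0; t < Luse; ++t) {
    int idx = batch(b, t);
    if (idx < 0 || idx >= A1) stop("sequence index %d outside alphabet range", idx);
    Xt.col(t) = W.E.row(idx).t();
  }
}

// [[Rcpp::export]]
List cpp_ognet_pass(List weights, IntegerMatrix batch, IntegerVector lengths,
                    IntegerVector filter_sizes, double dropout_p, bool training,
                    IntegerVector labels, bool compute_grads) {
  RNGScope rng;
  OgWeights W = unpack_ognet(weights, filter_sizes);
  const int B = batch.nrow(), Lmax = batch.ncol();
  const int nK = filter_sizes.size();
  const int F = W.Wk[0].n_cols;
  const int D = W.E.n_cols;
  const int Kmax = filter_sizes[nK - 1];
  if (Lmax < Kmax) stop("batch width %d smaller than largest filter size %d", Lmax, Kmax);

  arma::mat feat(B, nK * F, arma::fill::zeros);
  arma::umat amax(B, nK * F);       // argmax window per pooled unit
  arma::mat apre(B, nK * F);        // pre-activation at the argmax

  arma::mat Xt;
  for (int b = 0; b < B; ++b) {
    const int L = lengths[b];
    const int Luse = std::max(L, Kmax);
    embed_seq(W, batch, b, Luse, Xt);
    for (int i = 0; i < nK; ++i) {
      const int k = filter_sizes[i];
      const int nW = std::max(L - k + 1, 1);
      // im2col: columns of Xt are contiguous, so a window is one memcpy
      arma::mat At(k * D, nW);
      for (int p = 0; p < nW; ++p)
        std::memcpy(At.colptr(p), Xt.colptr(p), sizeof(double) * k * D);
      arma::mat Z = At.t() * W.Wk[i];
      Z.each_row() += W.bk[i].t();
      // SELU is strictly increasing: argmax of selu(Z) == argmax of Z
      for (int f = 0; f < F; ++f) {
        arma::uword p = Z.col(f).index_max();
        amax(b, i * F + f) = p;
        apre(b, i * F + f) = Z(p, f);
        feat(b, i * F + f) = selu(Z(p, f));
      }
    }
  }

  arma::mat mask;
  arma::mat featd = feat;
  const bool use_dropout = training && dropout_p > 0.0;
  if (use_dropout) {
    mask.set_size(B, nK * F);
    const double keep = 1.0 - dropout_p;
    for (arma::uword j = 0; j < mask.n_elem; ++j)
      mask(j) = (unif_rand() >= dropout_p) ? 1.0 / keep : 0.0;
    featd = feat % mask;
  }

  arma::mat logits = featd * W.Wout;
  logits.each_row() += W.bout;

  List out = List::create(Named("logits") = logits);
  if (labels.size() == 0) return out;

  arma::mat G;
  double loss = xent_and_grad(logits, labels, G);
  out["loss"] = loss;
  if (!compute_grads) return out;

  arma::mat d_out_w = featd.t() * G;
  arma::rowvec d_out_b = arma::sum(G, 0);
  arma::mat dfeat = G * W.Wout.t();
  if (use_dropout) dfeat %= mask;

  arma::mat dE(W.E.n_rows, D, arma::fill::zeros);
  std::vector<arma::mat> dWk(nK);
  std::vector<arma::vec> dbk(nK);
  for (int i = 0; i < nK; ++i) {
    dWk[i].zeros(W.Wk[i].n_rows, F);
    dbk[i].zeros(F);
  }

  arma::mat dXt;
  for (int b = 0; b < B; ++b) {
    const int L = lengths[b];
    const int Luse = std::max(L, Kmax);
    embed_seq(W, batch, b, Luse, Xt);
    dXt.zeros(D, Luse);
    for (int i = 0; i < nK; ++i) {
      const int k = filter_sizes[i];
      for (int f = 0; f < F; ++f) {
        const double g = dfeat(b, i * F + f);
        if (g == 0.0) continue;
        const double coef = g * selu_grad(apre(b, i * F + f));
        const arma::uword p = amax(b, i * F + f);
        // window block is contiguous in Xt / dXt memory
        arma::vec win(Xt.colptr(p), k * D, false, true);
        dWk[i].col(f) += coef * win;
        dbk[i](f) += coef;
        arma::vec dwin(dXt.colptr(p), k * D, false, true);
        dwin += coef * W.Wk[i].col(f);
      }
    }
    for (int t = 0; t < Luse; ++t)
      dE.row(batch(b, t)) += dXt.col(t).t();
  }
  dE.row(0).zeros();  // padding embedding is frozen

  List grads = List::create(Named("embedding") = dE,
                            Named("out_w") = d_out_w,
                            Named("out_b") = arma::vec(d_out_b.t()));
  for (int i = 0; i < nK; ++i) {
    std::string k = std::to_string(filter_sizes[i]);
    grads["conv_w_" + k] = dWk[i];
    grads["conv_b_" + k] = dbk[i];
  }
  out["grads"] = grads;
  return out;
}

// All post-SELU convolution activations over valid windows (used to verify
// the self-normalization property at initialization).
// [[Rcpp::export]]
NumericVector cpp_ognet_activations(List weights, IntegerMatrix batch,
                                    IntegerVector lengths, IntegerVector filter_sizes) {
  OgWeights W = unpack_ognet(weights, filter_sizes);
  const int B = batch.nrow();
  const int nK = filter_sizes.size();
  const int D = W.E.n_cols;
  const int Kmax = filter_sizes[nK - 1];
  std::vector<double> acts;
  arma::mat Xt;
  for (int b = 0; b < B; ++b) {
    const int L = lengths[b];
    const int Luse = std::max(L, Kmax);
    embed_seq(W, batch, b, Luse, Xt);
    for (int i = 0; i < nK; ++i) {
      const int k = filter_sizes[i];
      const int nW = std::max(L - k + 1, 1);
      arma::mat At(k * D, nW);
      for (int p = 0; p < nW; ++p)
        std::memcpy(At.colptr(p), Xt.colptr(p), sizeof(double) * k * D);
      arma::mat Z = At.t() * W.Wk[i];
      Z.each_row() += W.bk[i].t();
      for (arma::uword j = 0; j < Z.n_elem; ++j) acts.push_back(selu(Z(j)));
    }
  }
  return wrap(acts);
}

struct DfWeights {
  std::vector<arma::mat> Wk;   // (K*21) x F, row index j*21 + c
  std::vector<arma::vec> bk;   // F
  std::vector<arma::vec> gam, bet, rmean, rvar;  // F each
  arma::mat Wh;                // (nK*F) x H
  arma::rowvec bh;             // H
  arma::mat Wout;              // H x C
  arma::rowvec bout;           // C
};

static DfWeights unpack_deepfam(const List& w, const IntegerVector& ks) {
  DfWeights out;
  for (int i = 0; i < ks.size(); ++i) {
    std::string k = std::to_string(ks[i]);
    out.Wk.push_back(as<arma::mat>(w["conv_w_" + k]));
    out.bk.push_back(as<arma::vec>(w["conv_b_" + k]));
    out.gam.push_back(as<arma::vec>(w["bn_gamma_" + k]));
    out.bet.push_back(as<arma::vec>(w["bn_beta_" + k]));
    out.rmean.push_back(as<arma::vec>(w["bn_rmean_" + k]));
    out.rvar.push_back(as<arma::vec>(w["bn_rvar_" + k]));
  }
  out.Wh = as<arma::mat>(w["hidden_w"]);
  out.bh = as<arma::rowvec>(w["hidden_b"]);
  out.Wout = as<arma::mat>(w["out_w"]);
  out.bout = as<arma::rowvec>(w["out_b"]);
  return out;
}

// X: cube fixed_length x 21 x B (pseudo one-hot input)
// [[Rcpp::export]]
List cpp_deepfam_pass(List weights, arma::cube X, IntegerVector filter_sizes,
                      double dropout_p, bool training, IntegerVector labels,
                      bool compute_grads, double bn_eps, double bn_momentum) {
  RNGScope rng;
  DfWeights W = unpack_deepfam(weights, filter_sizes);
  const int B = X.n_slices;
  const int Lfix = X.n_rows;
  const int nK = filter_sizes.size();
  const int F = W.Wk[0].n_cols;

  std::vector<arma::cube> Zk(nK);            // pre-BN conv outputs
  std::vector<arma::vec> mu(nK), sd(nK);     // normalization statistics used
  arma::mat feat(B, nK * F, arma::fill::zeros);
  arma::umat amax(B, nK * F);

  for (int i = 0; i < nK; ++i) {
    const int k = filter_sizes[i];
    const int nW = Lfix - k + 1;
    if (nW < 1) stop("fixed_length %d smaller than filter size %d", Lfix, k);
    Zk[i].set_size(nW, F, B);
    for (int b = 0; b < B; ++b) {
      arma::mat Z(nW, F, arma::fill::zeros);
      const arma::mat& Xs = X.slice(b);
      for (int j = 0; j < k; ++j)
        Z += Xs.rows(j, j + nW - 1) * W.Wk[i].rows(j * 21, j * 21 + 20);
      Z.each_row() += W.bk[i].t();
      Zk[i].slice(b) = Z;
    }
    const double N = (double)B * nW;
    if (training) {
      arma::vec s(F, arma::fill::zeros), s2(F, arma::fill::zeros);
      for (int b = 0; b < B; ++b) {
        s += arma::sum(Zk[i].slice(b), 0).t();
        s2 += arma::sum(arma::square(Zk[i].slice(b)), 0).t();
      }
      mu[i] = s / N;
      arma::vec var = s2 / N - arma::square(mu[i]);
      var.transform([](double v) { return v < 0 ? 0.0 : v; });
      sd[i] = arma::sqrt(var + bn_eps);
      W.rmean[i] = (1.0 - bn_momentum) * W.rmean[i] + bn_momentum * mu[i];
      W.rvar[i] = (1.0 - bn_momentum) * W.rvar[i] + bn_momentum * var;
    } else {
      mu[i] = W.rmean[i];
      sd[i] = arma::sqrt(W.rvar[i] + bn_eps);
    }
    for (int b = 0; b < B; ++b) {
      const arma::mat& Z = Zk[i].slice(b);
      for (int f = 0; f < F; ++f) {
        arma::vec y = W.gam[i](f) * (Z.col(f) - mu[i](f)) / sd[i](f) + W.bet[i](f);
        y.transform([](double v) { return v > 0 ? v : 0.0; });
        arma::uword p = y.index_max();
        amax(b, i * F + f) = p;
        feat(b, i * F + f) = y(p);
      }
    }
  }

  arma::mat Hpre = feat * W.Wh;
  Hpre.each_row() += W.bh;
  arma::mat Hact = arma::clamp(Hpre, 0.0, arma::datum::inf);
  arma::mat mask;
  arma::mat Hd = Hact;
  const bool use_dropout = training && dropout_p > 0.0;
  if (use_dropout) {
    mask.set_size(Hact.n_rows, Hact.n_cols);
    const double keep = 1.0 - dropout_p;
    for (arma::uword j = 0; j < mask.n_elem; ++j)
      mask(j) = (unif_rand() >= dropout_p) ? 1.0 / keep : 0.0;
    Hd = Hact % mask;
  }
  arma::mat logits = Hd * W.Wout;
  logits.each_row() += W.bout;

  List out = List::create(Named("logits") = logits);
  if (training) {
    List rs;
    for (int i = 0; i < nK; ++i) {
      std::string k = std::to_string(filter_sizes[i]);
      rs["bn_rmean_" + k] = W.rmean[i];
      rs["bn_rvar_" + k] = W.rvar[i];
    }
    out["running_stats"] = rs;
  }
  if (labels.size() == 0) return out;

  arma::mat G;
  double loss = xent_and_grad(logits, labels, G);
  out["loss"] = loss;
  if (!compute_grads) return out;

  arma::mat d_out_w = Hd.t() * G;
  arma::rowvec d_out_b = arma::sum(G, 0);
  arma::mat dHd = G * W.Wout.t();
  if (use_dropout) dHd %= mask;
  arma::mat dHpre = dHd % (Hpre > 0);
  arma::mat d_hw = feat.t() * dHpre;
  arma::rowvec d_hb = arma::sum(dHpre, 0);
  arma::mat dfeat = dHpre * W.Wh.t();

  List grads = List::create(Named("hidden_w") = d_hw,
                            Named("hidden_b") = arma::vec(d_hb.t()),
                            Named("out_w") = d_out_w,
                            Named("out_b") = arma::vec(d_out_b.t()));

  for (int i = 0; i < nK; ++i) {
    const int k = filter_sizes[i];
    const int nW = Lfix - k + 1;
    const double N = (double)B * nW;
    // route pooled gradients; compute batch-norm statistic sums
    // S1_f = sum dy, S2_f = sum dy * zhat over pooled (argmax) entries;
    // ReLU gates entries whose pooled activation was exactly zero
    arma::vec S1(F, arma::fill::zeros), S2(F, arma::fill::zeros);
    arma::mat dy(B, F, arma::fill::zeros);  // gradient at the argmax entry
    for (int b = 0; b < B; ++b) {
      for (int f = 0; f < F; ++f) {
        double g = dfeat(b, i * F + f);
        if (g == 0.0 || feat(b, i * F + f) <= 0.0) continue;
        arma::uword p = amax(b, i * F + f);
        double zhat = (Zk[i](p, f, b) - mu[i](f)) / sd[i](f);
        dy(b, f) = g;
        S1(f) += g;
        S2(f) += g * zhat;
      }
    }
    arma::vec dgamma = S2, dbeta = S1;
    arma::mat dWki(W.Wk[i].n_rows, F, arma::fill::zeros);
    arma::vec dbki(F, arma::fill::zeros);
    if (training) {
      // exact backward through batch statistics:
      // dz = gam/sd * (dy - S1/N - zhat * S2/N) = a*z + c (+ gam/sd*dy at argmax)
      arma::vec a(F), cvec(F);
      for (int f = 0; f < F; ++f) {
        double gs = W.gam[i](f) / sd[i](f);
        a(f) = -gs * S2(f) / (N * sd[i](f));
        cvec(f) = -gs * S1(f) / N + gs * S2(f) * mu[i](f) / (N * sd[i](f));
      }
      for (int b = 0; b < B; ++b) {
        arma::mat dZ = Zk[i].slice(b);
        dZ.each_row() %= a.t();
        dZ.each_row() += cvec.t();
        for (int f = 0; f < F; ++f)
          if (dy(b, f) != 0.0)
            dZ(amax(b, i * F + f), f) += W.gam[i](f) / sd[i](f) * dy(b, f);
        const arma::mat& Xs = X.slice(b);
        for (int j = 0; j < k; ++j)
          dWki.rows(j * 21, j * 21 + 20) += Xs.rows(j, j + nW - 1).t() * dZ;
        dbki += arma::sum(dZ, 0).t();
      }
    } else {
      // frozen statistics (eval-mode gradients, used only for checks)
      for (int b = 0; b < B; ++b) {
        const arma::mat& Xs = X.slice(b);
        for (int f = 0; f < F; ++f) {
          if (dy(b, f) == 0.0) continue;
          double coef = W.gam[i](f) / sd[i](f) * dy(b, f);
          arma::uword p = amax(b, i * F + f);
          for (int j = 0; j < k; ++j)
            dWki.col(f).subvec(j * 21, j * 21 + 20) += coef * Xs.row(p + j).t();
          dbki(f) += coef;
        }
      }
    }
    std::string ks = std::to_string(k);
    grads["conv_w_" + ks] = dWki;
    grads["conv_b_" + ks] = dbki;
    grads["bn_gamma_" + ks] = dgamma;
    grads["bn_beta_" + ks] = dbeta;
  }
  out["grads"] = grads;
  return out;
}
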