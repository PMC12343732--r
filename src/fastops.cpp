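// Fast path for the spatial-domain nonlinearity (ISFT -> LeakyReLU -> SFT),
// the training-time bottleneck. Single-precision BLAS is ample here: the
// layer is re-projected onto the band-limited subspace either way, and the
// reference double-precision R implementation is kept and cross-checked in
// the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// (B*K) x C double, row index (k-1)*B + b  ->  (B*C) x K float
static arma::fmat kb_to_ck_f(const arma::mat &X, int B, int K, int C) {
  arma::fmat out((size_t)B * C, K);
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < C; ++c) {
      const double *src = X.colptr(c) + (size_t)k * B;
      float *dst = out.colptr(k) + (size_t)c * B;
      for (int b = 0; b < B; ++b) dst[b] = (float)src[b];
    }
  return out;
}

// (B*C) x K float -> (B*K) x C double
static arma::mat ck_to_kb_d(const arma::fmat &X, int B, int K, int C) {
  arma::mat out((size_t)B * K, C);
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < K; ++k) {
      const float *src = X.colptr(k) + (size_t)c * B;
      double *dst = out.colptr(c) + (size_t)k * B;
      for (int b = 0; b < B; ++b) dst[b] = (double)src[b];
    }
  return out;
}

// [[Rcpp::export]]
List nonlin_fwd_cpp(const arma::mat &X, int B, int K, int C,
                    const arma::mat &Ut, const arma::mat &Vt, double slope) {
  arma::fmat Xk = kb_to_ck_f(X, B, K, C);
  arma::fmat A = Xk * arma::conv_to<arma::fmat>::from(Ut);
  RawMatrix pos(A.n_rows, A.n_cols);
  const float s = (float)slope;
  unsigned char *pp = (unsigned char *)RAW(pos);
  for (size_t i = 0; i < A.n_elem; ++i) {
    bool p = A[i] >= 0.0f;
    pp[i] = p;
    if (!p) A[i] *= s;
  }
  arma::fmat Yk = A * arma::conv_to<arma::fmat>::from(Vt);
  return List::create(_["Y"] = ck_to_kb_d(Yk, B, K, C), _["pos"] = pos);
}

// [[Rcpp::export]]
arma::mat nonlin_bwd_cpp(const arma::mat &dY, const RawMatrix &pos,
                         int B, int K, int C,
                         const arma::mat &V, const arma::mat &U,
                         double slope) {
  arma::fmat dYk = kb_to_ck_f(dY, B, K, C);
  arma::fmat dA = dYk * arma::conv_to<arma::fmat>::from(V);
  const float s = (float)slope;
  const unsigned char *pp = (const unsigned char *)RAW(pos);
  for (size_t i = 0; i < dA.n_elem; ++i)
    if (!pp[i]) dA[i] *= s;
  arma::fmat dXk = dA * arma::conv_to<arma::fmat>::from(U);
  return ck_to_kb_d(dXk, B, K, C);
}

// ---- equivariant convolution (degree blocks are contiguous row ranges) ----

// [[Rcpp::export]]
arma::mat conv_fwd_cpp(const arma::mat &X, const arma::cube &W,
                       const Rcpp::Nullable<Rcpp::NumericVector> &bias,
                       int B, bool residual) {
  const int L = W.n_slices, c_out = W.n_rows;
  arma::mat Y(X.n_rows, c_out);
  size_t r0 = 0;
  for (int d = 0; d < L; ++d) {
    const int ml = 4 * d + 1;           // 2l+1 for l = 2d
    const size_t r1 = r0 + (size_t)ml * B - 1;
    Y.rows(r0, r1) = X.rows(r0, r1) * W.slice(d).t();
    r0 = r1 + 1;
  }
  if (bias.isNotNull()) {
    Rcpp::NumericVector b(bias);
    for (int c = 0; c < c_out; ++c)
      Y.submat(0, c, B - 1, c) += b[c];
  }
  if (residual) Y += X;
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv_bwd_cpp(const arma::mat &dY, const arma::mat &X,
                        const arma::cube &W, bool has_bias, int B,
                        bool residual) {
  const int L = W.n_slices;
  arma::mat dX(dY.n_rows, W.n_cols);
  arma::cube dW(W.n_rows, W.n_cols, L);
  size_t r0 = 0;
  for (int d = 0; d < L; ++d) {
    const int ml = 4 * d + 1;
    const size_t r1 = r0 + (size_t)ml * B - 1;
    dX.rows(r0, r1) = dY.rows(r0, r1) * W.slice(d);
    dW.slice(d) = dY.rows(r0, r1).t() * X.rows(r0, r1);
    r0 = r1 + 1;
  }
  Rcpp::List out = Rcpp::List::create(Rcpp::_["dX"] = dX,
                                      Rcpp::_["dW"] = dW);
  if (has_bias) {
    arma::rowvec db = arma::sum(dY.rows(0, B - 1), 0);
    out["db"] = Rcpp::NumericVector(db.begin(), db.end());
  }
  if (residual) out["dX"] = Rcpp::as<arma::mat>(out["dX"]) + dY;
  return out;
}

// ---- fused batch-norm + ReLU ----------------------------------------------

// [[Rcpp::export]]
Rcpp::List bn_relu_fwd_cpp(const arma::mat &X, const arma::vec &gamma,
                           const arma::vec &beta, arma::vec mean,
                           arma::vec var, bool training, double momentum,
                           double eps, bool relu) {
  const arma::uword n = X.n_rows, d = X.n_cols;
  arma::vec mu(d), v(d);
  if (training) {
    mu = arma::mean(X, 0).t();
    v = arma::mean(arma::square(X), 0).t() - arma::square(mu);
    mean = (1 - momentum) * mean + momentum * mu;
    var = (1 - momentum) * var + momentum * v;
  } else {
    mu = mean; v = var;
  }
  arma::vec istd = 1.0 / arma::sqrt(v + eps);
  arma::mat xhat(n, d), Y(n, d);
  for (arma::uword c = 0; c < d; ++c) {
    const double m_ = mu[c], is_ = istd[c], g_ = gamma[c], b_ = beta[c];
    const double *src = X.colptr(c);
    double *xh = xhat.colptr(c), *y = Y.colptr(c);
    for (arma::uword i = 0; i < n; ++i) {
      const double z = (src[i] - m_) * is_;
      xh[i] = z;
      double val = g_ * z + b_;
      if (relu && val < 0) val = 0;
      y[i] = val;
    }
  }
  return Rcpp::List::create(Rcpp::_["Y"] = Y, Rcpp::_["xhat"] = xhat,
                            Rcpp::_["istd"] = istd, Rcpp::_["mean"] = mean,
                            Rcpp::_["var"] = var);
}

// dY is the gradient w.r.t. the (possibly ReLU-ed) output; Y the forward
// output (used for the ReLU mask when relu = true).
// [[Rcpp::export]]
Rcpp::List bn_relu_bwd_cpp(const arma::mat &dY_in, const arma::mat &Y,
                           const arma::mat &xhat, const arma::vec &istd,
                           const arma::vec &gamma, bool relu) {
  arma::mat dY = dY_in;
  if (relu) dY.elem(arma::find(Y <= 0)).zeros();
  const arma::uword n = dY.n_rows;
  arma::vec dgamma = arma::sum(dY % xhat, 0).t();
  arma::vec dbeta = arma::sum(dY, 0).t();
  arma::mat dX(n, dY.n_cols);
  for (arma::uword c = 0; c < dY.n_cols; ++c) {
    const double g_ = gamma[c], is_ = istd[c];
    const double mdx = dbeta[c] / n, mdxx = dgamma[c] / n;
    const double *dy = dY.colptr(c), *xh = xhat.colptr(c);
    double *dx = dX.colptr(c);
    for (arma::uword i = 0; i < n; ++i)
      dx[i] = g_ * is_ * (dy[i] - mdx - xh[i] * mdxx);
  }
  return Rcpp::List::create(Rcpp::_["dX"] = dX, Rcpp::_["dgamma"] = dgamma,
                            Rcpp::_["dbeta"] = dbeta);
}

// ---- fused MLP stack (single precision) ------------------------------------
// layers: n_h x (linear -> BN -> ReLU), then final linear. Ws[i]: d_in x d_out.

// [[Rcpp::export]]
Rcpp::List mlp_stack_fwd_cpp(const arma::mat &X0, const Rcpp::List &Ws,
                             const Rcpp::List &bs, const Rcpp::List &gammas,
                             const Rcpp::List &betas, Rcpp::List means,
                             Rcpp::List vars, bool training, double momentum,
                             double eps) {
  const int n_h = gammas.size();
  arma::fmat cur = arma::conv_to<arma::fmat>::from(X0);
  Rcpp::List ins(n_h + 1), xhats(n_h), istds(n_h), ys(n_h);
  Rcpp::List new_means(n_h), new_vars(n_h);
  for (int l = 0; l < n_h; ++l) {
    ins[l] = cur;
    arma::fmat W = arma::conv_to<arma::fmat>::from(
      Rcpp::as<arma::mat>(Ws[l]));
    arma::fvec b = arma::conv_to<arma::fvec>::from(
      Rcpp::as<arma::vec>(bs[l]));
    arma::fmat H = cur * W;
    H.each_row() += b.t();
    arma::fvec gamma = arma::conv_to<arma::fvec>::from(
      Rcpp::as<arma::vec>(gammas[l]));
    arma::fvec beta = arma::conv_to<arma::fvec>::from(
      Rcpp::as<arma::vec>(betas[l]));
    arma::vec mean = Rcpp::as<arma::vec>(means[l]);
    arma::vec var = Rcpp::as<arma::vec>(vars[l]);
    const arma::uword n = H.n_rows, d = H.n_cols;
    arma::fvec mu(d), v(d);
    if (training) {
      mu = arma::mean(H, 0).t();
      v = arma::mean(arma::square(H), 0).t() - arma::square(mu);
      for (arma::uword c = 0; c < d; ++c) {
        mean[c] = (1 - momentum) * mean[c] + momentum * (double)mu[c];
        var[c] = (1 - momentum) * var[c] + momentum * (double)v[c];
      }
    } else {
      mu = arma::conv_to<arma::fvec>::from(mean);
      v = arma::conv_to<arma::fvec>::from(var);
    }
    arma::fvec istd = 1.0f / arma::sqrt(v + (float)eps);
    arma::fmat xhat(n, d), Y(n, d);
    for (arma::uword c = 0; c < d; ++c) {
      const float m_ = mu[c], is_ = istd[c], g_ = gamma[c], be_ = beta[c];
      const float *src = H.colptr(c);
      float *xh = xhat.colptr(c), *y = Y.colptr(c);
      for (arma::uword i = 0; i < n; ++i) {
        const float z = (src[i] - m_) * is_;
        xh[i] = z;
        float val = g_ * z + be_;
        if (val < 0) val = 0;
        y[i] = val;
      }
    }
    xhats[l] = xhat; istds[l] = istd; ys[l] = Y;
    new_means[l] = mean; new_vars[l] = var;
    cur = Y;
  }
  ins[n_h] = cur;
  arma::fmat Wo = arma::conv_to<arma::fmat>::from(
    Rcpp::as<arma::mat>(Ws[n_h]));
  arma::fvec bo = arma::conv_to<arma::fvec>::from(
    Rcpp::as<arma::vec>(bs[n_h]));
  arma::fmat out = cur * Wo;
  out.each_row() += bo.t();
  return Rcpp::List::create(
    Rcpp::_["out"] = arma::conv_to<arma::mat>::from(out),
    Rcpp::_["ins"] = ins, Rcpp::_["xhats"] = xhats,
    Rcpp::_["istds"] = istds, Rcpp::_["ys"] = ys,
    Rcpp::_["means"] = new_means, Rcpp::_["vars"] = new_vars);
}

// [[Rcpp::export]]
Rcpp::List mlp_stack_bwd_cpp(const arma::mat &dout, const Rcpp::List &cache,
                             const Rcpp::List &Ws, const Rcpp::List &gammas) {
  const int n_h = gammas.size();
  Rcpp::List ins = cache["ins"], xhats = cache["xhats"],
    istds = cache["istds"], ys = cache["ys"];
  Rcpp::List dWs(n_h + 1), dbs(n_h + 1), dgammas(n_h), dbetas(n_h);
  arma::fmat dcur = arma::conv_to<arma::fmat>::from(dout);
  arma::fmat last_in = Rcpp::as<arma::fmat>(ins[n_h]);
  arma::fmat Wo = arma::conv_to<arma::fmat>::from(
    Rcpp::as<arma::mat>(Ws[n_h]));
  dWs[n_h] = arma::conv_to<arma::mat>::from(last_in.t() * dcur);
  arma::frowvec dbo = arma::sum(dcur, 0);
  dbs[n_h] = arma::conv_to<arma::vec>::from(dbo.t());
  dcur = dcur * Wo.t();
  for (int l = n_h - 1; l >= 0; --l) {
    arma::fmat Y = Rcpp::as<arma::fmat>(ys[l]);
    arma::fmat xhat = Rcpp::as<arma::fmat>(xhats[l]);
    arma::fvec istd = Rcpp::as<arma::fvec>(istds[l]);
    arma::fvec gamma = arma::conv_to<arma::fvec>::from(
      Rcpp::as<arma::vec>(gammas[l]));
    dcur.elem(arma::find(Y <= 0)).zeros();
    const arma::uword n = dcur.n_rows, d = dcur.n_cols;
    arma::fvec dgamma = arma::sum(dcur % xhat, 0).t();
    arma::fvec dbeta = arma::sum(dcur, 0).t();
    arma::fmat dH(n, d);
    for (arma::uword c = 0; c < d; ++c) {
      const float g_ = gamma[c], is_ = istd[c];
      const float mdx = dbeta[c] / n, mdxx = dgamma[c] / n;
      const float *dy = dcur.colptr(c), *xh = xhat.colptr(c);
      float *dh = dH.colptr(c);
      for (arma::uword i = 0; i < n; ++i)
        dh[i] = g_ * is_ * (dy[i] - mdx - xh[i] * mdxx);
    }
    dgammas[l] = arma::conv_to<arma::vec>::from(dgamma);
    dbetas[l] = arma::conv_to<arma::vec>::from(dbeta);
    arma::fmat in_l = Rcpp::as<arma::fmat>(ins[l]);
    arma::fmat W = arma::conv_to<arma::fmat>::from(
      Rcpp::as<arma::mat>(Ws[l]));
    dWs[l] = arma::conv_to<arma::mat>::from(in_l.t() * dH);
    arma::frowvec db = arma::sum(dH, 0);
    dbs[l] = arma::conv_to<arma::vec>::from(db.t());
    dcur = dH * W.t();
  }
  return Rcpp::List::create(Rcpp::_["dWs"] = dWs, Rcpp::_["dbs"] = dbs,
                            Rcpp::_["dgammas"] = dgammas,
                            Rcpp::_["dbetas"] = dbetas);
}

// ---- flat AdamW step -------------------------------------------------------
// Updates p, m, v in one pass; decoupled weight decay on masked entries.

// [[Rcpp::export]]
Rcpp::List adamw_flat_cpp(const arma::vec &p, const arma::vec &g,
                          const arma::vec &m, const arma::vec &v,
                          const arma::uvec &decay_idx, int t, double lr,
                          double weight_decay, double beta1, double beta2,
                          double eps) {
  const double c1 = 1.0 / (1.0 - std::pow(beta1, t));
  const double c2 = 1.0 / (1.0 - std::pow(beta2, t));
  arma::vec m2(p.n_elem), v2(p.n_elem), p2(p.n_elem);
  for (arma::uword i = 0; i < p.n_elem; ++i) {
    m2[i] = beta1 * m[i] + (1 - beta1) * g[i];
    v2[i] = beta2 * v[i] + (1 - beta2) * g[i] * g[i];
    p2[i] = p[i] - lr * (c1 * m2[i] / (std::sqrt(c2 * v2[i]) + eps));
  }
  if (weight_decay > 0)
    for (arma::uword j = 0; j < decay_idx.n_elem; ++j)
      p2[decay_idx[j]] *= (1 - lr * weight_decay);
  return Rcpp::List::create(Rcpp::_["p"] = p2, Rcpp::_["m"] = m2,
                            Rcpp::_["v"] = v2);
}
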