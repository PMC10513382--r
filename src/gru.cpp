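// Gated recurrent (GRU) cell: forward rollout and backpropagation-through-
// time gradient of the semi-gradient TD loss. Weight rows are grouped by
// gate as [reset; update; candidate] (each block H rows), matching the
// conventional stacked parameterisation:
//   r_t = sigmoid(Wi_r o_t + bi_r + Wh_r z_{t-1} + bh_r)
//   u_t = sigmoid(Wi_u o_t + bi_u + Wh_u z_{t-1} + bh_u)
//   n_t = tanh(Wi_n o_t + bi_n + r_t % (Wh_n z_{t-1} + bh_n))
//   z_t = (1 - u_t) % n_t + u_t % z_{t-1}
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline vec sigmoid(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export]]
arma::mat cpp_gru_forward(const arma::mat& Wi, const arma::mat& Wh,
                          const arma::vec& bi, const arma::vec& bh,
                          const arma::mat& obs, const arma::vec& z0) {
  const uword H = Wh.n_cols;
  const uword T = obs.n_rows;
  mat Z(T, H);
  vec z = z0;
  for (uword t = 0; t < T; ++t) {
    vec ai = Wi * obs.row(t).t() + bi;
    vec ah = Wh * z + bh;
    vec r = sigmoid(ai.subvec(0, H - 1) + ah.subvec(0, H - 1));
    vec u = sigmoid(ai.subvec(H, 2 * H - 1) + ah.subvec(H, 2 * H - 1));
    vec n = tanh(ai.subvec(2 * H, 3 * H - 1) + r % ah.subvec(2 * H, 3 * H - 1));
    z = (1.0 - u) % n + u % z;
    Z.row(t) = z.t();
  }
  return Z;
}

// Semi-gradient TD loss over one episode (hidden state starts at zero):
//   V_t = w' z_t + w0,  delta_t = r_{t+1} + gamma * V_{t+1} - V_t
//   L = sum_{t=1}^{T-1} delta_t^2, gradient taken through V_t only
// (the bootstrapped target is treated as a constant). Returns the summed
// loss, the number of TD terms, and gradients for all parameters.
// [[Rcpp::export]]
Rcpp::List cpp_gru_episode_grad(const arma::mat& Wi, const arma::mat& Wh,
                                const arma::vec& bi, const arma::vec& bh,
                                const arma::vec& w, double w0,
                                const arma::mat& obs, const arma::vec& rew,
                                double gamma) {
  const uword H = Wh.n_cols;
  const uword T = obs.n_rows;
  // forward pass, caching gate activations
  mat Z(H, T), Rg(H, T), Ug(H, T), Ng(H, T), HHn(H, T);
  vec z(H, fill::zeros);
  mat Zprev(H, T);
  for (uword t = 0; t < T; ++t) {
    Zprev.col(t) = z;
    vec ai = Wi * obs.row(t).t() + bi;
    vec ah = Wh * z + bh;
    vec r = sigmoid(ai.subvec(0, H - 1) + ah.subvec(0, H - 1));
    vec u = sigmoid(ai.subvec(H, 2 * H - 1) + ah.subvec(H, 2 * H - 1));
    vec hhn = ah.subvec(2 * H, 3 * H - 1);
    vec n = tanh(ai.subvec(2 * H, 3 * H - 1) + r % hhn);
    z = (1.0 - u) % n + u % z;
    Rg.col(t) = r; Ug.col(t) = u; Ng.col(t) = n; HHn.col(t) = hhn;
    Z.col(t) = z;
  }
  // values and TD errors
  vec V(T);
  for (uword t = 0; t < T; ++t) V(t) = dot(w, Z.col(t)) + w0;
  double loss = 0.0;
  vec dV(T, fill::zeros);
  for (uword t = 0; t + 1 < T; ++t) {
    double delta = rew(t + 1) + gamma * V(t + 1) - V(t);
    loss += delta * delta;
    dV(t) = -2.0 * delta;  // dL/dV_t (target detached)
  }
  // backward pass
  mat dWi(size(Wi), fill::zeros), dWh(size(Wh), fill::zeros);
  vec dbi(3 * H, fill::zeros), dbh(3 * H, fill::zeros);
  vec dw(H, fill::zeros);
  double dw0 = 0.0;
  vec dh(H, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    dh += dV(tt) * w;
    dw += dV(tt) * Z.col(tt);
    dw0 += dV(tt);
    vec r = Rg.col(tt), u = Ug.col(tt), n = Ng.col(tt), hhn = HHn.col(tt);
    vec hprev = Zprev.col(tt);
    vec dz = dh % (hprev - n);
    vec dn = dh % (1.0 - u);
    vec dh_prev = dh % u;
    vec dn_pre = dn % (1.0 - n % n);
    vec dhh_n = dn_pre % r;
    vec dr = dn_pre % hhn;
    vec dr_pre = dr % r % (1.0 - r);
    vec dz_pre = dz % u % (1.0 - u);
    rowvec x = obs.row(tt);
    dWi.rows(0, H - 1) += dr_pre * x;
    dWi.rows(H, 2 * H - 1) += dz_pre * x;
    dWi.rows(2 * H, 3 * H - 1) += dn_pre * x;
    dWh.rows(0, H - 1) += dr_pre * hprev.t();
    dWh.rows(H, 2 * H - 1) += dz_pre * hprev.t();
    dWh.rows(2 * H, 3 * H - 1) += dhh_n * hprev.t();
    dbi.subvec(0, H - 1) += dr_pre;
    dbi.subvec(H, 2 * H - 1) += dz_pre;
    dbi.subvec(2 * H, 3 * H - 1) += dn_pre;
    dbh.subvec(0, H - 1) += dr_pre;
    dbh.subvec(H, 2 * H - 1) += dz_pre;
    dbh.subvec(2 * H, 3 * H - 1) += dhh_n;
    dh_prev += Wh.rows(0, H - 1).t() * dr_pre +
               Wh.rows(H, 2 * H - 1).t() * dz_pre +
               Wh.rows(2 * H, 3 * H - 1).t() * dhh_n;
    dh = dh_prev;
  }
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("n") = (double)(T > 0 ? T - 1 : 0),
    Rcpp::Named("dWi") = dWi, Rcpp::Named("dWh") = dWh,
    Rcpp::Named("dbi") = dbi, Rcpp::Named("dbh") = dbh,
    Rcpp::Named("dw") = dw, Rcpp::Named("dw0") = dw0);
}

// Batched version of the episode gradient: processes a batch of episodes
// in lockstep (padded to the longest episode; padded steps are masked out
// of the loss and contribute zero gradient). Returns summed loss and
// gradients over the whole batch plus the number of TD terms.
// [[Rcpp::export]]
Rcpp::List cpp_gru_batch_grad(const arma::mat& Wi, const arma::mat& Wh,
                              const arma::vec& bi, const arma::vec& bh,
                              const arma::vec& w, double w0,
                              const Rcpp::List& obs_list,
                              const Rcpp::List& rew_list,
                              double gamma) {
  const uword H = Wh.n_cols;
  const uword B = obs_list.size();
  std::vector<mat> obs(B);
  std::vector<vec> rew(B);
  uword Tmax = 0;
  for (uword b = 0; b < B; ++b) {
    obs[b] = Rcpp::as<mat>(obs_list[b]);
    rew[b] = Rcpp::as<vec>(rew_list[b]);
    Tmax = std::max(Tmax, obs[b].n_rows);
  }
  // padded inputs: X[t] is 2 x B
  cube X(2, B, Tmax, fill::zeros);
  for (uword b = 0; b < B; ++b)
    for (uword t = 0; t < obs[b].n_rows; ++t)
      X.slice(t).col(b) = obs[b].row(t).t();

  cube Zs(H, B, Tmax), Rs(H, B, Tmax), Us(H, B, Tmax), Ns(H, B, Tmax),
       HHs(H, B, Tmax), Zp(H, B, Tmax);
  const mat Wh_r = Wh.rows(0, H - 1), Wh_u = Wh.rows(H, 2 * H - 1),
            Wh_n = Wh.rows(2 * H, 3 * H - 1);
  const mat Wi_r = Wi.rows(0, H - 1), Wi_u = Wi.rows(H, 2 * H - 1),
            Wi_n = Wi.rows(2 * H, 3 * H - 1);
  const vec bi_r = bi.subvec(0, H - 1), bi_u = bi.subvec(H, 2 * H - 1),
            bi_n = bi.subvec(2 * H, 3 * H - 1);
  const vec bh_r = bh.subvec(0, H - 1), bh_u = bh.subvec(H, 2 * H - 1),
            bh_n = bh.subvec(2 * H, 3 * H - 1);
  mat Z(H, B, fill::zeros);
  for (uword t = 0; t < Tmax; ++t) {
    Zp.slice(t) = Z;
    const mat& Xt = X.slice(t);
    mat R = 1.0 / (1.0 + exp(-(Wi_r * Xt + Wh_r * Z +
                               repmat(bi_r + bh_r, 1, B))));
    mat U = 1.0 / (1.0 + exp(-(Wi_u * Xt + Wh_u * Z +
                               repmat(bi_u + bh_u, 1, B))));
    mat HHn = Wh_n * Z + repmat(bh_n, 1, B);
    mat N = tanh(Wi_n * Xt + repmat(bi_n, 1, B) + R % HHn);
    Z = (1.0 - U) % N + U % Z;
    Rs.slice(t) = R; Us.slice(t) = U; Ns.slice(t) = N; HHs.slice(t) = HHn;
    Zs.slice(t) = Z;
  }
  // values, TD errors, masked loss
  mat V(Tmax, B), dV(Tmax, B, fill::zeros);
  for (uword t = 0; t < Tmax; ++t)
    V.row(t) = w.t() * Zs.slice(t) + w0;
  double loss = 0.0;
  double n_terms = 0.0;
  for (uword b = 0; b < B; ++b) {
    const uword L = obs[b].n_rows;
    for (uword t = 0; t + 1 < L; ++t) {
      double delta = rew[b](t + 1) + gamma * V(t + 1, b) - V(t, b);
      loss += delta * delta;
      dV(t, b) = -2.0 * delta;
      n_terms += 1.0;
    }
  }
  // backward
  mat dWi(size(Wi), fill::zeros), dWh(size(Wh), fill::zeros);
  vec dbi(3 * H, fill::zeros), dbh(3 * H, fill::zeros);
  vec dw(H, fill::zeros);
  double dw0 = 0.0;
  mat dh(H, B, fill::zeros);
  for (uword tt = Tmax; tt-- > 0;) {
    rowvec dVt = dV.row(tt);
    dh += w * dVt;
    dw += Zs.slice(tt) * dVt.t();
    dw0 += accu(dVt);
    const mat& R = Rs.slice(tt); const mat& U = Us.slice(tt);
    const mat& N = Ns.slice(tt); const mat& HHn = HHs.slice(tt);
    const mat& hprev = Zp.slice(tt);
    mat dz = dh % (hprev - N);
    mat dn_pre = (dh % (1.0 - U)) % (1.0 - N % N);
    mat dhh_n = dn_pre % R;
    mat dr_pre = (dn_pre % HHn) % R % (1.0 - R);
    mat dz_pre = dz % U % (1.0 - U);
    const mat& Xt = X.slice(tt);
    dWi.rows(0, H - 1) += dr_pre * Xt.t();
    dWi.rows(H, 2 * H - 1) += dz_pre * Xt.t();
    dWi.rows(2 * H, 3 * H - 1) += dn_pre * Xt.t();
    dWh.rows(0, H - 1) += dr_pre * hprev.t();
    dWh.rows(H, 2 * H - 1) += dz_pre * hprev.t();
    dWh.rows(2 * H, 3 * H - 1) += dhh_n * hprev.t();
    dbi.subvec(0, H - 1) += sum(dr_pre, 1);
    dbi.subvec(H, 2 * H - 1) += sum(dz_pre, 1);
    dbi.subvec(2 * H, 3 * H - 1) += sum(dn_pre, 1);
    dbh.subvec(0, H - 1) += sum(dr_pre, 1);
    dbh.subvec(H, 2 * H - 1) += sum(dz_pre, 1);
    dbh.subvec(2 * H, 3 * H - 1) += sum(dhh_n, 1);
    dh = dh % U + Wh_r.t() * dr_pre + Wh_u.t() * dz_pre + Wh_n.t() * dhh_n;
  }
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss, Rcpp::Named("n") = n_terms,
    Rcpp::Named("dWi") = dWi, Rcpp::Named("dWh") = dWh,
    Rcpp::Named("dbi") = dbi, Rcpp::Named("dbh") = dbh,
    Rcpp::Named("dw") = dw, Rcpp::Named("dw0") = dw0);
}
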