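// Joint log-posterior and gradient of the multi-source (multi-task)
// hierarchical regression with a Finnish horseshoe prior on the shared
// coefficient vector, on the unconstrained scale used by the NUTS sampler.
//
// Parameter vector theta (length G + G*D + G + 1 + D [+ m]):
//   z        (G)    non-centered shared coefficients: beta = z * lambda~ * tau
//   u        (G*D)  non-centered source offsets:
//                     coupling "scaled":  beta^(d) = beta + s0 * lambda~ * tau * u_d
//                     coupling "fixed":   beta^(d) = beta + s0 * u_d
//   eta_l    (G)    log local scales lambda_g   ~ C+(0, 1)
//   eta_t    (1)    log global scale tau        ~ C+(0, tau0(sigma))
//   eta_s    (D)    log noise sd sigma_d        ~ IG(a, b)
//   w        (m)    per-drug weights            ~ N(w_loc, sqrt(vw))  [multi-task]
//
// tau0 = p0/(G - p0) * sum_d sigma_d / sqrt(N_d)      (per-source grouping)
//      = p0/(G - p0) * sum_d sigma_d / sqrt(sum N_d)  (pooled grouping)
// Optional regularized slab of scale c: lambda~ = c l / sqrt(c^2 + tau^2 l^2).

#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

struct Task {
  int d;        // 0-based source index
  int drug;     // 0-based drug index
  bool all;     // uses every row of X[d]
  uvec rows;    // 0-based row subset otherwise
  vec y;
};

struct BmsrModel {
  std::vector<mat> X;
  std::vector<Task> tasks;
  int G = 0, D = 0, m = 1;
  double s0 = 0.5, vw = 0.25, w_loc = 0.5, p0 = 10.0;
  double a_sig = 1.0, b_sig = 1.0, slab = -1.0;
  int grouping = 0;  // 0 = per-source, 1 = pooled
  int coupling = 0;  // 0 = scaled (offset sd rides on lambda~ tau), 1 = fixed
  vec Nd;
  bool w_free = false;
  int npar() const { return G + G * D + G + 1 + D + (w_free ? m : 0); }
};

// [[Rcpp::export]]
SEXP bmsr_model_build(List data) {
  BmsrModel* mod = new BmsrModel();
  List Xl = data["X"];
  mod->D = Xl.size();
  for (int d = 0; d < mod->D; ++d) mod->X.push_back(as<mat>(Xl[d]));
  mod->G = mod->X[0].n_cols;
  List tl = data["tasks"];
  for (int k = 0; k < tl.size(); ++k) {
    List t = tl[k];
    Task tk;
    tk.d = as<int>(t["d"]) - 1;
    tk.drug = as<int>(t["drug"]) - 1;
    tk.y = as<vec>(t["y"]);
    IntegerVector rows = t["rows"];
    tk.all = ((unsigned) rows.size() == mod->X[tk.d].n_rows);
    if (tk.all) {
      // also require identity ordering to use the fast path
      for (int j = 0; j < rows.size(); ++j)
        if (rows[j] != j + 1) { tk.all = false; break; }
    }
    if (!tk.all) tk.rows = as<uvec>(t["rows"]) - 1;
    mod->tasks.push_back(tk);
  }
  mod->m = as<int>(data["m"]);
  mod->s0 = as<double>(data["s0"]);
  mod->vw = as<double>(data["vw"]);
  mod->w_loc = as<double>(data["w_loc"]);
  mod->p0 = as<double>(data["p0"]);
  mod->a_sig = as<double>(data["a_sig"]);
  mod->b_sig = as<double>(data["b_sig"]);
  mod->slab = as<double>(data["slab"]);
  mod->grouping = as<int>(data["grouping"]);
  mod->coupling = as<int>(data["coupling"]);
  mod->Nd = as<vec>(data["Nd"]);
  mod->w_free = as<bool>(data["w_free"]);
  XPtr<BmsrModel> ptr(mod, true);
  return ptr;
}

// [[Rcpp::export]]
int bmsr_model_npar(SEXP ptr_) {
  XPtr<BmsrModel> ptr(ptr_);
  return ptr->npar();
}

// [[Rcpp::export]]
List bmsr_lp_grad(SEXP ptr_, const arma::vec& theta) {
  XPtr<BmsrModel> ptr(ptr_);
  const BmsrModel& M = *ptr;
  const int G = M.G, D = M.D, m = M.m;

  int off = 0;
  vec z = theta.subvec(off, off + G - 1); off += G;
  mat u(G, D);
  for (int d = 0; d < D; ++d) { u.col(d) = theta.subvec(off, off + G - 1); off += G; }
  vec eta_l = theta.subvec(off, off + G - 1); off += G;
  double eta_t = theta(off); off += 1;
  vec eta_s = theta.subvec(off, off + D - 1); off += D;
  vec w(m, fill::ones);
  if (M.w_free) { w = theta.subvec(off, off + m - 1); off += m; }

  vec lambda = exp(eta_l);
  double tau = std::exp(eta_t);
  vec sigma = exp(eta_s);
  vec sig2 = square(sigma);

  const double c0 = M.p0 / (G - M.p0);
  double tau0;
  if (M.grouping == 0) tau0 = c0 * accu(sigma / sqrt(M.Nd));
  else tau0 = c0 * accu(sigma) / std::sqrt(accu(M.Nd));

  // lambda~ and partials
  vec lt(G), dlt_dl(G);        // d lambda~ / d lambda
  double slab2 = M.slab * M.slab;
  vec dlt_dtau_fac(G, fill::zeros);  // d lambda~ / d tau
  bool use_slab = (M.slab > 0);
  if (use_slab) {
    vec denom = sqrt(slab2 + tau * tau * square(lambda));
    lt = M.slab * lambda / denom;
    dlt_dl = M.slab * slab2 / pow(denom, 3);
    dlt_dtau_fac = -M.slab * lambda % square(lambda) * tau / pow(denom, 3);
  } else {
    lt = lambda;
    dlt_dl.ones();
  }

  vec kappa = lt * tau;                  // per-gene coefficient prior scale
  vec beta = z % kappa;
  mat beta_d(G, D);
  for (int d = 0; d < D; ++d) {
    if (M.coupling == 0) beta_d.col(d) = beta + M.s0 * (kappa % u.col(d));
    else beta_d.col(d) = beta + M.s0 * u.col(d);
  }

  double lp = 0.0;
  mat S(G, D, fill::zeros);            // d lp / d beta^(d)
  vec grad_sig_lik(D, fill::zeros);    // d lp_lik / d eta_s (likelihood part)
  vec grad_w(m, fill::zeros);

  for (size_t k = 0; k < M.tasks.size(); ++k) {
    const Task& tk = M.tasks[k];
    const int d = tk.d;
    vec Xb, r;
    if (tk.all) Xb = M.X[d] * beta_d.col(d);
    else Xb = M.X[d].rows(tk.rows) * beta_d.col(d);
    r = tk.y - w(tk.drug) * Xb;
    const double rss = dot(r, r);
    const int n = tk.y.n_elem;
    lp += -n * eta_s(d) - 0.5 * rss / sig2(d);
    vec xtr;
    if (tk.all) xtr = M.X[d].t() * r;
    else xtr = M.X[d].rows(tk.rows).t() * r;
    S.col(d) += (w(tk.drug) / sig2(d)) * xtr;
    grad_sig_lik(d) += -n + rss / sig2(d);
    if (M.w_free) grad_w(tk.drug) += dot(Xb, r) / sig2(d);
  }

  // priors
  lp += -0.5 * dot(z, z) - 0.5 * accu(square(u));
  lp += accu(eta_l) - accu(log1p(square(lambda)));
  const double t_ratio = tau / tau0;
  lp += eta_t - std::log(tau0) - std::log1p(t_ratio * t_ratio);
  lp += accu(-M.a_sig * eta_s - M.b_sig / sigma);  // IG(a,b) + log Jacobian
  if (M.w_free) lp += -0.5 * accu(square(w - M.w_loc)) / M.vw;

  // gradient assembly
  vec Sbeta = sum(S, 1);                         // d lp / d beta (shared part)
  vec grad_z = Sbeta % kappa - z;
  mat grad_u(G, D);
  for (int d = 0; d < D; ++d) {
    if (M.coupling == 0) grad_u.col(d) = M.s0 * (kappa % S.col(d)) - u.col(d);
    else grad_u.col(d) = M.s0 * S.col(d) - u.col(d);
  }

  // chain of kappa = lambda~ * tau into every coefficient that uses it:
  // C_g = sum_d S_gd * (z_g [+ s0 u_gd under scaled coupling])
  vec C;
  if (M.coupling == 0) {
    C.zeros(G);
    for (int d = 0; d < D; ++d) C += S.col(d) % (z + M.s0 * u.col(d));
  } else {
    C = Sbeta % z;
  }

  // eta_lambda: chain through kappa, plus half-Cauchy prior + Jacobian
  vec dkappa_detal = tau * dlt_dl % lambda;
  vec grad_etal = C % dkappa_detal + 1.0 - 2.0 * square(lambda) / (1.0 + square(lambda));

  // eta_tau: chain through kappa, plus half-Cauchy(tau0) prior + Jacobian
  vec dkappa_detat = (lt + tau * dlt_dtau_fac) * tau;
  const double t2 = t_ratio * t_ratio;
  double grad_etat = dot(C, dkappa_detat) + 1.0 - 2.0 * t2 / (1.0 + t2);

  // eta_sigma: likelihood + IG prior + Jacobian + tau0 channel
  const double dlp_dtau0 = (-1.0 + 2.0 * t2 / (1.0 + t2)) / tau0;
  vec grad_etas(D);
  for (int d = 0; d < D; ++d) {
    double k_d = (M.grouping == 0) ? c0 / std::sqrt(M.Nd(d))
                                   : c0 / std::sqrt(accu(M.Nd));
    grad_etas(d) = grad_sig_lik(d) - M.a_sig + M.b_sig / sigma(d) +
                   dlp_dtau0 * k_d * sigma(d);
  }

  vec grad(M.npar());
  off = 0;
  grad.subvec(off, off + G - 1) = grad_z; off += G;
  for (int d = 0; d < D; ++d) { grad.subvec(off, off + G - 1) = grad_u.col(d); off += G; }
  grad.subvec(off, off + G - 1) = grad_etal; off += G;
  grad(off) = grad_etat; off += 1;
  grad.subvec(off, off + D - 1) = grad_etas; off += D;
  if (M.w_free) {
    grad.subvec(off, off + m - 1) = grad_w - (w - M.w_loc) / M.vw;
    off += m;
  }

  return List::create(_["logp"] = lp, _["grad"] = grad);
}

// Deterministic pieces needed on the R side to reconstruct constrained draws.
// [[Rcpp::export]]
List bmsr_constrain(SEXP ptr_, const arma::vec& theta) {
  XPtr<BmsrModel> ptr(ptr_);
  const BmsrModel& M = *ptr;
  const int G = M.G, D = M.D, m = M.m;
  int off = 0;
  vec z = theta.subvec(off, off + G - 1); off += G;
  mat u(G, D);
  for (int d = 0; d < D; ++d) { u.col(d) = theta.subvec(off, off + G - 1); off += G; }
  vec lambda = exp(theta.subvec(off, off + G - 1)); off += G;
  double tau = std::exp(theta(off)); off += 1;
  vec sigma = exp(theta.subvec(off, off + D - 1)); off += D;
  vec w(m, fill::ones);
  if (M.w_free) w = theta.subvec(off, off + m - 1);
  vec lt = lambda;
  if (M.slab > 0) lt = M.slab * lambda / sqrt(M.slab * M.slab + tau * tau * square(lambda));
  vec kappa = lt * tau;
  vec beta = z % kappa;
  mat beta_d(G, D);
  for (int d = 0; d < D; ++d) {
    if (M.coupling == 0) beta_d.col(d) = beta + M.s0 * (kappa % u.col(d));
    else beta_d.col(d) = beta + M.s0 * u.col(d);
  }
  const double c0 = M.p0 / (G - M.p0);
  double tau0 = (M.grouping == 0) ? c0 * accu(sigma / sqrt(M.Nd))
                                  : c0 * accu(sigma) / std::sqrt(accu(M.Nd));
  return List::create(_["beta"] = beta, _["beta_source"] = beta_d,
                      _["lambda"] = lambda, _["tau"] = tau, _["tau0"] = tau0,
                      _["sigma"] = sigma, _["w"] = w);
}
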