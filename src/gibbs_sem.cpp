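// Gibbs sampler for the three-trait recursive structural equation model:
// traits (ADG_AL, ADG_R, M) with structural coefficients lambda_AL, lambda_R
// on M, fixed effects, litter/cage/genomic random effects with 3x3
// covariance matrices (L0, C0, G0) and a diagonal residual covariance R0.
// The acyclic structure plus diagonal R0 gives a unit Jacobian, so the model
// is sampled as a mixed model on the structurally transformed data, with the
// mediator entering the growth-trait rows as a regressor.
//
// The genomic effects are sampled in the eigenbasis of the relationship
// matrix G = U diag(d) U'; there the full conditional factorizes into n
// independent 3x3 Gaussians, which keeps each sweep O(n^2). All 3x3 solves
// are hand-rolled Cholesky factorizations: they sit in per-animal and
// per-level loops where allocation overhead dominates.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double OVERFLOW_GUARD = 1e12;

// Expand per-level effects to per-animal vectors.
static vec pick(const vec& v, const uvec& idx) { return v.elem(idx); }

// Draw x ~ N(P^-1 rhs, P^-1) for a 3x3 SPD precision P, in place into out.
static inline void mvn3(const double P[3][3], const double rhs[3],
                        double out[3], int iter) {
  const double l11s = P[0][0];
  if (l11s <= 0.0) Rcpp::stop("non-PD full-conditional precision at iteration %d", iter);
  const double l11 = std::sqrt(l11s);
  const double l21 = P[1][0] / l11;
  const double l31 = P[2][0] / l11;
  const double d22 = P[1][1] - l21 * l21;
  if (d22 <= 0.0) Rcpp::stop("non-PD full-conditional precision at iteration %d", iter);
  const double l22 = std::sqrt(d22);
  const double l32 = (P[2][1] - l31 * l21) / l22;
  const double d33 = P[2][2] - l31 * l31 - l32 * l32;
  if (d33 <= 0.0) Rcpp::stop("non-PD full-conditional precision at iteration %d", iter);
  const double l33 = std::sqrt(d33);
  // forward solve L y = rhs, backward solve L' mu = y
  const double y0 = rhs[0] / l11;
  const double y1 = (rhs[1] - l21 * y0) / l22;
  const double y2 = (rhs[2] - l31 * y0 - l32 * y1) / l33;
  const double mu2 = y2 / l33;
  const double mu1 = (y1 - l32 * mu2) / l22;
  const double mu0 = (y0 - l21 * mu1 - l31 * mu2) / l11;
  // noise: solve L' x = z so that cov(x) = P^-1
  const double z0 = R::norm_rand(), z1 = R::norm_rand(), z2 = R::norm_rand();
  const double x2 = z2 / l33;
  const double x1 = (z1 - l32 * x2) / l22;
  const double x0 = (z0 - l21 * x1 - l31 * x2) / l11;
  out[0] = mu0 + x0;
  out[1] = mu1 + x1;
  out[2] = mu2 + x2;
}

// Wishart(nu, V) via Bartlett, then invert: inverse-Wishart(nu, S), V = S^-1.
static mat riwish3(double nu, const mat& S, int iter) {
  mat V;
  if (!inv_sympd(V, S)) {
    Rcpp::stop("non-PD sufficient-statistic matrix at iteration %d", iter);
  }
  mat L = chol(V, "lower");
  mat A(3, 3, fill::zeros);
  for (int i = 0; i < 3; ++i) {
    A(i, i) = std::sqrt(R::rchisq(nu - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  mat W = L * A;
  mat X = W * W.t();
  mat out;
  if (!inv_sympd(out, X)) {
    Rcpp::stop("singular Wishart draw at iteration %d", iter);
  }
  return symmatu((out + out.t()) / 2.0);
}

// Sample per-level random effects (litters or cages) from their independent
// 3x3 full conditionals. res must hold the data residuals with every other
// effect removed; counts holds the number of animals per level.
static void sample_level_effects(mat& eff, const mat& res, const uvec& level,
                                 const ivec& counts, const mat& Pinv,
                                 const vec& r0, int iter) {
  const int n_lev = eff.n_rows;
  const int n = res.n_rows;
  mat S(n_lev, 3, fill::zeros);
  for (int t = 0; t < 3; ++t) {
    const double* rc = res.colptr(t);
    double* sc = S.colptr(t);
    for (int i = 0; i < n; ++i) sc[level(i)] += rc[i];
  }
  for (int j = 0; j < n_lev; ++j) {
    double P[3][3], rhs[3], out[3];
    for (int a = 0; a < 3; ++a) {
      for (int bi = 0; bi < 3; ++bi) P[a][bi] = Pinv(a, bi);
      P[a][a] += counts(j) / r0(a);
      rhs[a] = S(j, a) / r0(a);
    }
    mvn3(P, rhs, out, iter);
    eff(j, 0) = out[0]; eff(j, 1) = out[1]; eff(j, 2) = out[2];
  }
}

// [[Rcpp::export]]
Rcpp::List gibbs_sem_cpp(const arma::vec& y_al_obs,
                         const arma::vec& y_r_obs,
                         const arma::vec& y_m,
                         const arma::uvec& miss_al,
                         const arma::uvec& miss_r,
                         const arma::mat& X,
                         const arma::uvec& litter,
                         const arma::uvec& cage,
                         const arma::mat& Ueig,
                         const arma::vec& deig,
                         int n_iter, int burn_in, int thin,
                         const arma::mat& S_L, const arma::mat& S_C,
                         const arma::mat& S_G, double nu0,
                         const arma::vec& res_scale, double nu_e,
                         double prior_var_b, double prior_var_lambda,
                         bool save_effects,
                         Rcpp::Nullable<Rcpp::List> init_state,
                         bool return_state) {
  const int n = y_m.n_elem;
  const int p = X.n_cols;
  const int n_lit = litter.max() + 1;
  const int n_cage = cage.max() + 1;

  const double prec_b0 = std::isfinite(prior_var_b) ? 1.0 / prior_var_b : 0.0;
  const double prec_l0 = std::isfinite(prior_var_lambda) ? 1.0 / prior_var_lambda : 0.0;

  // state
  mat b(p, 3, fill::zeros);
  mat le(n_lit, 3, fill::zeros);
  mat ce(n_cage, 3, fill::zeros);
  mat u(n, 3, fill::zeros);
  mat util(n, 3, fill::zeros); // u in the eigenbasis of G
  double lam_al = 0.0, lam_r = 0.0;
  mat L0 = S_L, C0 = S_C, G0 = S_G;
  vec r0 = res_scale;
  if (nu0 > 4.0) { L0 /= (nu0 - 4.0); C0 /= (nu0 - 4.0); G0 /= (nu0 - 4.0); }

  vec y_al = y_al_obs, y_r = y_r_obs;
  {
    // initialize augmented slots at the observed trait means
    uvec oal = find(miss_al == 0), orr = find(miss_r == 0);
    double m_al = oal.n_elem ? mean(y_al_obs(oal)) : 0.0;
    double m_r = orr.n_elem ? mean(y_r_obs(orr)) : 0.0;
    y_al(find(miss_al == 1)).fill(m_al);
    y_r(find(miss_r == 1)).fill(m_r);
  }

  if (init_state.isNotNull()) {
    Rcpp::List st(init_state);
    b = Rcpp::as<mat>(st["b"]);
    le = Rcpp::as<mat>(st["l"]);
    ce = Rcpp::as<mat>(st["c"]);
    u = Rcpp::as<mat>(st["u"]);
    lam_al = Rcpp::as<double>(st["lambda_al"]);
    lam_r = Rcpp::as<double>(st["lambda_r"]);
    L0 = Rcpp::as<mat>(st["L0"]);
    C0 = Rcpp::as<mat>(st["C0"]);
    G0 = Rcpp::as<mat>(st["G0"]);
    r0 = Rcpp::as<vec>(st["r0"]);
    util = Ueig.t() * u;
  }

  const mat XtX = X.t() * X;
  const vec inv_d = 1.0 / deig;
  // cross-products of the augmented design [X, y_m] for the growth traits
  mat XtYm(p + 1, p + 1);
  XtYm.submat(0, 0, p - 1, p - 1) = XtX;
  XtYm.submat(0, p, p - 1, p) = X.t() * y_m;
  XtYm.submat(p, 0, p, p - 1) = XtYm.submat(0, p, p - 1, p).t();
  XtYm(p, p) = dot(y_m, y_m);

  ivec lit_counts(n_lit, fill::zeros), cage_counts(n_cage, fill::zeros);
  for (int i = 0; i < n; ++i) {
    lit_counts(litter(i))++;
    cage_counts(cage(i))++;
  }

  const int n_save = (n_iter - burn_in) / thin;
  const int n_par = 2 + 6 + 6 + 6 + 3;
  mat draws(n_save, n_par);
  mat b_draws;
  if (save_effects) b_draws.set_size(n_save, p * 3);
  int saved = 0;

  Rcpp::RNGScope scope;

  for (int it = 1; it <= n_iter; ++it) {
    if (it % 512 == 0) Rcpp::checkUserInterrupt();

    // (i) data augmentation of the structurally missing phenotype
    {
      vec eta_al = X * b.col(0) + pick(le.col(0), litter) + pick(ce.col(0), cage) +
                   u.col(0) + lam_al * y_m;
      vec eta_r = X * b.col(1) + pick(le.col(1), litter) + pick(ce.col(1), cage) +
                  u.col(1) + lam_r * y_m;
      const double s_al = std::sqrt(r0(0)), s_r = std::sqrt(r0(1));
      for (int i = 0; i < n; ++i) {
        if (miss_al(i)) y_al(i) = eta_al(i) + s_al * R::norm_rand();
        if (miss_r(i)) y_r(i) = eta_r(i) + s_r * R::norm_rand();
      }
    }

    // per-animal sum of litter + cage effects
    mat lc(n, 3);
    for (int t = 0; t < 3; ++t)
      lc.col(t) = pick(le.col(t), litter) + pick(ce.col(t), cage);

    // (ii)+(iii) location block per growth trait: fixed effects and the
    // structural coefficient sampled jointly (they share the mean structure,
    // so blocking them removes the dominant posterior correlation); the
    // mediator trait updates its fixed effects alone.
    for (int t = 0; t < 2; ++t) {
      vec res = (t == 0 ? y_al : y_r) - lc.col(t) - u.col(t);
      mat P = XtYm / r0(t);
      P.diag() += prec_b0;
      P(p, p) += prec_l0 - prec_b0;
      mat Rch;
      if (!chol(Rch, P)) Rcpp::stop("non-PD location-block precision at iteration %d", it);
      vec rhs(p + 1);
      rhs.head(p) = X.t() * res;
      rhs(p) = dot(y_m, res);
      rhs /= r0(t);
      vec mu = solve(trimatu(Rch), solve(trimatl(Rch.t()), rhs));
      vec z(p + 1);
      for (int k = 0; k <= p; ++k) z(k) = R::norm_rand();
      vec draw = mu + solve(trimatu(Rch), z);
      b.col(t) = draw.head(p);
      (t == 0 ? lam_al : lam_r) = draw(p);
    }
    {
      vec res = y_m - lc.col(2) - u.col(2);
      mat P = XtX / r0(2);
      P.diag() += prec_b0;
      mat Rch;
      if (!chol(Rch, P)) Rcpp::stop("non-PD fixed-effect precision at iteration %d", it);
      vec rhs = X.t() * res / r0(2);
      vec mu = solve(trimatu(Rch), solve(trimatl(Rch.t()), rhs));
      vec z(p);
      for (int k = 0; k < p; ++k) z(k) = R::norm_rand();
      b.col(2) = mu + solve(trimatu(Rch), z);
    }
    const mat xb = X * b;

    // structurally transformed responses (unit Jacobian)
    mat w(n, 3);
    w.col(0) = y_al - lam_al * y_m;
    w.col(1) = y_r - lam_r * y_m;
    w.col(2) = y_m;

    // (ii) litter, cage and genomic effects
    mat L0inv, C0inv, G0inv;
    if (!inv_sympd(L0inv, L0) || !inv_sympd(C0inv, C0) || !inv_sympd(G0inv, G0)) {
      Rcpp::stop("non-PD covariance draw at iteration %d", it);
    }
    {
      mat res = w - xb - u;
      for (int t = 0; t < 3; ++t) res.col(t) -= pick(ce.col(t), cage);
      sample_level_effects(le, res, litter, lit_counts, L0inv, r0, it);
    }
    {
      mat res = w - xb - u;
      for (int t = 0; t < 3; ++t) res.col(t) -= pick(le.col(t), litter);
      sample_level_effects(ce, res, cage, cage_counts, C0inv, r0, it);
    }
    {
      mat res = w - xb;
      for (int t = 0; t < 3; ++t)
        res.col(t) -= pick(le.col(t), litter) + pick(ce.col(t), cage);
      mat rtil = Ueig.t() * res;
      for (int k = 0; k < n; ++k) {
        double P[3][3], rhs[3], out[3];
        const double idk = inv_d(k);
        for (int a = 0; a < 3; ++a) {
          for (int bi = 0; bi < 3; ++bi) P[a][bi] = G0inv(a, bi) * idk;
          P[a][a] += 1.0 / r0(a);
          rhs[a] = rtil(k, a) / r0(a);
        }
        mvn3(P, rhs, out, it);
        util(k, 0) = out[0]; util(k, 1) = out[1]; util(k, 2) = out[2];
      }
      u = Ueig * util;
    }

    // (iv) covariance matrices from inverse-Wishart full conditionals
    L0 = riwish3(nu0 + n_lit, S_L + le.t() * le, it);
    C0 = riwish3(nu0 + n_cage, S_C + ce.t() * ce, it);
    G0 = riwish3(nu0 + n, S_G + util.t() * (util.each_col() % inv_d), it);

    // (v) residual variances from scaled inverse chi-square
    {
      mat e(n, 3);
      e.col(0) = y_al - lam_al * y_m;
      e.col(1) = y_r - lam_r * y_m;
      e.col(2) = y_m;
      e -= xb + u;
      for (int t = 0; t < 3; ++t) {
        e.col(t) -= pick(le.col(t), litter) + pick(ce.col(t), cage);
        double sse = dot(e.col(t), e.col(t));
        r0(t) = (nu_e * res_scale(t) + sse) / R::rchisq(nu_e + n);
      }
    }

    if (L0.diag().max() > OVERFLOW_GUARD || C0.diag().max() > OVERFLOW_GUARD ||
        G0.diag().max() > OVERFLOW_GUARD || r0.max() > OVERFLOW_GUARD) {
      Rcpp::stop("divergent chain at iteration %d: a variance exceeded the overflow guard; use stronger priors", it);
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && saved < n_save) {
      int c0i = 0;
      draws(saved, c0i++) = lam_al;
      draws(saved, c0i++) = lam_r;
      const mat* mats[3] = { &L0, &C0, &G0 };
      for (int mi = 0; mi < 3; ++mi) {
        const mat& M = *mats[mi];
        draws(saved, c0i++) = M(0, 0);
        draws(saved, c0i++) = M(1, 0);
        draws(saved, c0i++) = M(1, 1);
        draws(saved, c0i++) = M(2, 0);
        draws(saved, c0i++) = M(2, 1);
        draws(saved, c0i++) = M(2, 2);
      }
      for (int t = 0; t < 3; ++t) draws(saved, c0i++) = r0(t);
      if (save_effects) {
        for (int t = 0; t < 3; ++t)
          for (int k = 0; k < p; ++k) b_draws(saved, t * p + k) = b(k, t);
      }
      ++saved;
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("draws") = draws,
      Rcpp::Named("b_draws") = save_effects ? Rcpp::wrap(b_draws) : R_NilValue);
  if (return_state) {
    out["state"] = Rcpp::List::create(
        Rcpp::Named("b") = b, Rcpp::Named("l") = le, Rcpp::Named("c") = ce,
        Rcpp::Named("u") = u, Rcpp::Named("lambda_al") = lam_al,
        Rcpp::Named("lambda_r") = lam_r, Rcpp::Named("L0") = L0,
        Rcpp::Named("C0") = C0, Rcpp::Named("G0") = G0,
        Rcpp::Named("r0") = r0);
  }
  return out;
}
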