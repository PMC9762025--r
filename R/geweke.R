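# Internal helpers for joint-distribution (prior-invariance) validation of
# the sampler: run raw Gibbs sweeps from a given state on given data, and
# draw from the priors. Used by the test suite.

# One or more Gibbs sweeps starting from `state`; returns the updated state.
sem_sweeps <- function(y_al, y_r, y_m, X, litter0, cage0, eig, config, state,
                       n_sweeps = 1L) {
  miss_al <- as.integer(is.na(y_al)); miss_r <- as.integer(is.na(y_r))
  y_al[is.na(y_al)] <- 0; y_r[is.na(y_r)] <- 0
  v <- config$empirical_var
  S0 <- diag(config$cov_scale_frac * v)
  res <- gibbs_sem_cpp(y_al, y_r, y_m, miss_al, miss_r, X, litter0, cage0,
                       eig$vectors, eig$values,
                       as.integer(n_sweeps), as.integer(n_sweeps - 1L), 1L,
                       S0, S0, S0, config$nu0,
                       config$res_scale_frac * v, config$nu_e,
                       config$prior_var_b, config$prior_var_lambda,
                       FALSE, state, TRUE)
  res$state
}

# Inverse-Wishart(nu, S) draw through stats::rWishart (independent of the
# C++ Bartlett sampler, so it doubles as its oracle).
rinvwishart <- function(nu, S) {
  solve(stats::rWishart(1, nu, solve(S))[, , 1])
}

# Scaled inverse chi-square(nu, s2) draw.
rsinvchisq <- function(nu, s2) {
  nu * s2 / stats::rchisq(1, nu)
}

# Draw a full parameter state from the (proper) priors of `config`.
sem_prior_draw <- function(p, n_litters, n_cages, n, config, eig) {
  v <- config$empirical_var
  S0 <- diag(config$cov_scale_frac * v)
  L0 <- rinvwishart(config$nu0, S0)
  C0 <- rinvwishart(config$nu0, S0)
  G0 <- rinvwishart(config$nu0, S0)
  r0 <- vapply(config$res_scale_frac * v, function(s) rsinvchisq(config$nu_e, s),
               numeric(1))
  stopifnot(is.finite(config$prior_var_b), is.finite(config$prior_var_lambda))
  rmvn_rows <- function(k, cov) matrix(stats::rnorm(k * 3), k, 3) %*% chol(cov)
  u_til <- rmvn_rows(n, G0) * sqrt(eig$values)
  list(b = matrix(stats::rnorm(p * 3, 0, sqrt(config$prior_var_b)), p, 3),
       l = rmvn_rows(n_litters, L0),
       c = rmvn_rows(n_cages, C0),
       u = eig$vectors %*% u_til,
       lambda_al = stats::rnorm(1, 0, sqrt(config$prior_var_lambda)),
       lambda_r = stats::rnorm(1, 0, sqrt(config$prior_var_lambda)),
       L0 = L0, C0 = C0, G0 = G0, r0 = r0)
}

# Simulate complete data y | state (the generative conditional of the model).
sem_data_draw <- function(state, X, litter0, cage0) {
  n <- nrow(X)
  li <- litter0 + 1L; ca <- cage0 + 1L
  e <- matrix(stats::rnorm(n * 3), n, 3) %*% diag(sqrt(as.numeric(state$r0)))
  y_m <- X %*% state$b[, 3] + state$l[li, 3] + state$c[ca, 3] + state$u[, 3] + e[, 3]
  y_al <- X %*% state$b[, 1] + state$lambda_al * y_m +
    state$l[li, 1] + state$c[ca, 1] + state$u[, 1] + e[, 1]
  y_r <- X %*% state$b[, 2] + state$lambda_r * y_m +
    state$l[li, 2] + state$c[ca, 2] + state$u[, 2] + e[, 2]
  list(y_al = as.numeric(y_al), y_r = as.numeric(y_r), y_m = as.numeric(y_m))
}
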