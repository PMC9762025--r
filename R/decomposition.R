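#' Structural-coefficient matrix of the recursive model
#'
#' The three traits are ordered (ADG_AL, ADG_R, M). The abundance M affects
#' both growth traits; nothing feeds back into M, so the only free entries of
#' the 3x3 structural matrix are (1,3) and (2,3).
#'
#' @param lambda_al,lambda_r Structural coefficients (g/day per CSS unit).
#' @return 3x3 matrix Lambda.
#' @export
lambda_matrix <- function(lambda_al, lambda_r) {
  stopifnot(is.finite(lambda_al), is.finite(lambda_r))
  L <- matrix(0, 3, 3, dimnames = list(trait_names(), trait_names()))
  L[1, 3] <- lambda_al
  L[2, 3] <- lambda_r
  L
}

trait_names <- function() c("AL", "R", "M")

#' Reduced-model (starred) covariance transform
#'
#' Maps a structural-model covariance matrix to its reduced-model counterpart:
#' `(I - Lambda)^-1 theta0 (I - Lambda)^-T`. Because the causal structure is
#' acyclic, `I - Lambda` is unit-triangular and always invertible. Element
#' (3,3) is invariant: the mediator's own variance is untouched by the
#' transform.
#'
#' @param theta0 Symmetric 3x3 covariance matrix in trait order (AL, R, M).
#' @param lambda_al,lambda_r Structural coefficients.
#' @return The transformed symmetric 3x3 matrix.
#' @export
transform_covariance <- function(theta0, lambda_al, lambda_r) {
  theta0 <- as.matrix(theta0)
  stopifnot(nrow(theta0) == 3, ncol(theta0) == 3)
  if (max(abs(theta0 - t(theta0))) > 1e-8 * max(1, max(abs(theta0)))) {
    stop("theta0 must be symmetric", call. = FALSE)
  }
  # (I - Lambda)^-1 is I + Lambda for this acyclic pattern
  B <- diag(3)
  B[1, 3] <- lambda_al
  B[2, 3] <- lambda_r
  out <- B %*% theta0 %*% t(B)
  (out + t(out)) / 2
}

#' Total, direct and indirect genetic variance of a growth trait
#'
#' Scalar expansion of the reduced-model transform for the trait's genetic
#' variance: `direct` is the genetic variance free of mediation, `indirect`
#' is the microbiota-mediated term `2 lambda cov(u_t, u_M) + lambda^2 var(u_M)`,
#' and `total = direct + indirect` equals the corresponding starred entry
#' exactly.
#'
#' @param g0 Symmetric 3x3 genetic covariance matrix (AL, R, M order).
#' @param lambda_al,lambda_r Structural coefficients.
#' @param trait `"AL"` or `"R"`.
#' @return Named numeric vector `c(total, direct, indirect)`.
#' @export
genetic_variance_parts <- function(g0, lambda_al, lambda_r, trait = c("AL", "R")) {
  trait <- match.arg(trait)
  g0 <- as.matrix(g0)
  t_idx <- if (trait == "AL") 1L else 2L
  lam <- if (trait == "AL") lambda_al else lambda_r
  direct <- g0[t_idx, t_idx]
  indirect <- 2 * lam * g0[t_idx, 3] + lam^2 * g0[3, 3]
  c(total = direct + indirect, direct = direct, indirect = indirect)
}

#' Total, direct and mediated genetic covariances
#'
#' Scalar expansions for the three genetic covariances of the model. For each
#' growth trait t, the covariance with the mediator splits into a direct part
#' `cov(u_t, u_M)` and a mediated part `lambda_t var(u_M)`; the covariance
#' between the two growth traits carries the mediated term
#' `lambda_AL cov(u_M, u_R) + lambda_R cov(u_M, u_AL) + lambda_AL lambda_R var(u_M)`.
#' Each total equals the matching starred matrix entry exactly.
#'
#' @inheritParams genetic_variance_parts
#' @return Named list of numeric vectors: `al_r` (total, direct, mediated),
#'   `al_m` and `r_m` (total, direct, indirect).
#' @export
genetic_covariance_parts <- function(g0, lambda_al, lambda_r) {
  g0 <- as.matrix(g0)
  med_al_r <- lambda_al * g0[3, 2] + lambda_r * g0[3, 1] + lambda_al * lambda_r * g0[3, 3]
  ind_al_m <- lambda_al * g0[3, 3]
  ind_r_m <- lambda_r * g0[3, 3]
  list(
    al_r = c(total = g0[1, 2] + med_al_r, direct = g0[1, 2], mediated = med_al_r),
    al_m = c(total = g0[1, 3] + ind_al_m, direct = g0[1, 3], indirect = ind_al_m),
    r_m = c(total = g0[2, 3] + ind_r_m, direct = g0[2, 3], indirect = ind_r_m))
}

#' Heritability of a growth trait under the structural or reduced model
#'
#' The denominator sums the litter, cage, genomic and residual variances of
#' the trait (the only variance sources in the model). `mode = "direct"` uses
#' the structural (unstarred) components; `mode = "total"` transforms every
#' component matrix to its reduced-model (starred) form first, so both the
#' genetic variance and the phenotypic variance include the mediated part.
#'
#' @param l0,c0,g0,r0 Symmetric 3x3 covariance matrices for litter, cage,
#'   genomic and residual effects (trait order AL, R, M).
#' @param lambda_al,lambda_r Structural coefficients.
#' @param trait `"AL"`, `"R"` or `"M"`.
#' @param mode `"direct"` or `"total"`.
#' @return Heritability in `[0, 1]`.
#' @export
heritability <- function(l0, c0, g0, r0, lambda_al = 0, lambda_r = 0,
                         trait = c("AL", "R", "M"), mode = c("direct", "total")) {
  trait <- match.arg(trait)
  mode <- match.arg(mode)
  t_idx <- match(trait, trait_names())
  if (mode == "total") {
    l0 <- transform_covariance(l0, lambda_al, lambda_r)
    c0 <- transform_covariance(c0, lambda_al, lambda_r)
    g0 <- transform_covariance(g0, lambda_al, lambda_r)
    r0 <- transform_covariance(r0, lambda_al, lambda_r)
  }
  num <- g0[t_idx, t_idx]
  den <- num + l0[t_idx, t_idx] + c0[t_idx, t_idx] + r0[t_idx, t_idx]
  if (den <= 0) stop("non-positive phenotypic variance", call. = FALSE)
  num / den
}

#' Standardize a structural coefficient to trait SD units
#'
#' Expresses the expected change in the growth trait, per one-unit increase
#' in CSS-normalized abundance, in phenotypic standard deviations.
#'
#' @param lambda_mean Posterior mean of the structural coefficient (g/day per
#'   CSS unit).
#' @param trait_sd Phenotypic standard deviation of the trait (g/day).
#' @return Effect in SD units.
#' @export
standardize_effect <- function(lambda_mean, trait_sd) {
  if (any(!is.finite(trait_sd)) || any(trait_sd <= 0)) {
    stop("trait_sd must be positive", call. = FALSE)
  }
  lambda_mean / trait_sd
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(prob * n)` of the sorted
#' draws. Ties in window width break toward the lowest starting index, so the
#' result is deterministic.
#'
#' @param draws Numeric vector of posterior draws (at least 20).
#' @param prob Target probability content (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  draws <- as.numeric(draws)
  n <- length(draws)
  if (n < 20) stop("need at least 20 draws for an HPD interval", call. = FALSE)
  stopifnot(prob > 0, prob < 1)
  x <- sort(draws)
  m <- ceiling(prob * n)
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths) # which.min takes the first minimum: lowest start wins
  c(lower = x[i], upper = x[i + m - 1])
}

#' Is a posterior distribution different from zero?
#'
#' The significance rule of the analysis: a structural coefficient is called
#' statistically different from zero when its HPD interval excludes zero.
#'
#' @inheritParams hpd_interval
#' @return Logical flag.
#' @export
is_significant <- function(draws, prob = 0.95) {
  h <- hpd_interval(draws, prob)
  h[["lower"]] > 0 || h[["upper"]] < 0
}

#' Is a standardized effect practically relevant?
#'
#' Effects of at least `threshold` phenotypic SD in absolute value (boundary
#' included) are flagged as relevant. Relevance is a magnitude call on the
#' posterior mean and is independent of the HPD significance call.
#'
#' @param std_effect Effect in SD units (from [standardize_effect()]).
#' @param threshold Relevance threshold in SD units (default 0.2).
#' @return Logical flag (vectorized).
#' @export
classify_relevant <- function(std_effect, threshold = 0.2) {
  abs(std_effect) >= threshold
}

#' Draw-by-draw posterior decomposition of a fitted model
#'
#' Applies the reduced-model algebra to every saved posterior draw and
#' summarizes: total/direct/indirect genetic variances and covariances,
#' direct and total heritabilities, SD-standardized effects, HPD intervals
#' and significance/relevance flags per growth trait. Summaries are posterior
#' means of per-draw quantities (the decomposition is nonlinear in lambda, so
#' plugging in posterior means would bias it).
#'
#' @param fit A `sem_fit` from [fit_sem()].
#' @param trait_sd Named numeric vector `c(AL = ..., R = ...)` of phenotypic
#'   SDs used for standardization; defaults to the SDs of the observed
#'   phenotypes stored in the fit.
#' @param hpd_prob HPD probability content (default 0.95).
#' @param relevance_threshold Relevance cutoff in SD units (default 0.2).
#' @return A `sem_decomposition`: tibble with one row per growth trait.
#' @export
decompose_posterior <- function(fit, trait_sd = NULL, hpd_prob = 0.95,
                                relevance_threshold = 0.2) {
  stopifnot(inherits(fit, "sem_fit"))
  d <- fit$draws
  if (is.null(trait_sd)) trait_sd <- fit$trait_sd
  stopifnot(all(c("AL", "R") %in% names(trait_sd)))

  per_trait <- purrr::map(c(AL = "AL", R = "R"), function(tr) {
    lam <- if (tr == "AL") d$lambda_AL else d$lambda_R
    g_dir <- if (tr == "AL") d$G0_11 else d$G0_22
    g_tm <- if (tr == "AL") d$G0_31 else d$G0_32
    g_mm <- d$G0_33
    indirect <- 2 * lam * g_tm + lam^2 * g_mm
    total <- g_dir + indirect
    cov_dir <- g_tm
    cov_ind <- lam * g_mm
    h2_direct <- vapply(seq_len(nrow(d)), function(i) {
      heritability(draw_mat(d, "L0", i), draw_mat(d, "C0", i),
                   draw_mat(d, "G0", i), draw_mat(d, "R0", i),
                   d$lambda_AL[i], d$lambda_R[i], trait = tr, mode = "direct")
    }, numeric(1))
    h2_total <- vapply(seq_len(nrow(d)), function(i) {
      heritability(draw_mat(d, "L0", i), draw_mat(d, "C0", i),
                   draw_mat(d, "G0", i), draw_mat(d, "R0", i),
                   d$lambda_AL[i], d$lambda_R[i], trait = tr, mode = "total")
    }, numeric(1))
    h <- hpd_interval(lam, hpd_prob)
    std <- standardize_effect(mean(lam), trait_sd[[tr]])
    tibble::tibble(
      trait = tr,
      lambda_mean = mean(lam), lambda_median = stats::median(lam),
      lambda_hpd_lower = h[["lower"]], lambda_hpd_upper = h[["upper"]],
      std_effect = std,
      significant = is_significant(lam, hpd_prob),
      relevant = classify_relevant(std, relevance_threshold),
      gvar_total = mean(total), gvar_direct = mean(g_dir),
      gvar_indirect = mean(indirect),
      gcov_m_total = mean(cov_dir + cov_ind), gcov_m_direct = mean(cov_dir),
      gcov_m_indirect = mean(cov_ind),
      h2_direct = mean(h2_direct), h2_total = mean(h2_total))
  })

  med_al_r <- d$lambda_AL * d$G0_32 + d$lambda_R * d$G0_31 +
    d$lambda_AL * d$lambda_R * d$G0_33
  out <- dplyr::bind_rows(per_trait)
  attr(out, "otu_id") <- fit$otu_id
  attr(out, "trait_sd") <- trait_sd
  attr(out, "hpd_prob") <- hpd_prob
  attr(out, "relevance_threshold") <- relevance_threshold
  attr(out, "gcov_al_r") <- c(total = mean(d$G0_21 + med_al_r),
                              direct = mean(d$G0_21), mediated = mean(med_al_r))
  attr(out, "h2_m") <- mean(d$G0_33 / (d$G0_33 + d$L0_33 + d$C0_33 + d$R0_33))
  class(out) <- c("sem_decomposition", class(out))
  out
}

# Rebuild a 3x3 covariance matrix from one row of a draws tibble.
draw_mat <- function(d, prefix, i) {
  if (prefix == "R0") {
    return(diag(c(d$R0_11[i], d$R0_22[i], d$R0_33[i])))
  }
  g <- function(nm) d[[paste0(prefix, "_", nm)]][i]
  m <- matrix(c(g("11"), g("21"), g("31"),
                g("21"), g("22"), g("32"),
                g("31"), g("32"), g("33")), 3, 3)
  m
}
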