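#' Chain configuration for the Gibbs sampler
#'
#' Desk-scale defaults (20,000 iterations, 5,000 burn-in, thinning 10) keep a
#' single fit interactive; production runs of 1,000,000 / 300,000 / 100 are a
#' configuration away. Priors are weakly informative and proper: an
#' inverse-Wishart for each 3x3 random-effect covariance matrix and a scaled
#' inverse chi-square for each residual variance, both centred on a fraction
#' of the empirical phenotype variances; fixed effects and structural
#' coefficients carry flat priors by default (`prior_var_b` / `prior_var_lambda`
#' may be set finite for a proper Gaussian prior).
#'
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Iterations discarded before saving (`burn_in < n_iter`).
#' @param thin Keep one of every `thin` post-burn-in draws.
#' @param seed Integer seed; a fixed seed makes the chain bit-reproducible.
#' @param nu0 Inverse-Wishart degrees of freedom for L0, C0, G0 (default 5).
#' @param cov_scale_frac Fraction of the empirical phenotype variance placed on
#'   the diagonal of each inverse-Wishart scale matrix (default 0.5).
#' @param nu_e Residual scaled-inverse-chi-square degrees of freedom (default 4).
#' @param res_scale_frac Fraction of the empirical variance used as the
#'   residual prior scale (default 0.5).
#' @param prior_var_b,prior_var_lambda Gaussian prior variances for fixed
#'   effects and structural coefficients; `Inf` (default) means flat.
#' @param save_effects Also save fixed-effect draws.
#' @return A `sem_chain_config` list.
#' @export
sem_chain_config <- function(n_iter = 20000, burn_in = 5000, thin = 10,
                             seed = 1L, nu0 = 5, cov_scale_frac = 0.5,
                             nu_e = 4, res_scale_frac = 0.5,
                             prior_var_b = Inf, prior_var_lambda = Inf,
                             save_effects = FALSE) {
  stopifnot(burn_in < n_iter, thin >= 1, n_iter >= 1, nu0 > 2, nu_e > 0,
            cov_scale_frac > 0, res_scale_frac > 0)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 nu0 = nu0, cov_scale_frac = cov_scale_frac, nu_e = nu_e,
                 res_scale_frac = res_scale_frac, prior_var_b = prior_var_b,
                 prior_var_lambda = prior_var_lambda,
                 save_effects = isTRUE(save_effects)),
            class = "sem_chain_config")
}

# Design matrix for the systematic effects: full batch-farm dummies plus a
# weaning-weight-class contrast (full dummies for both would be rank deficient).
sem_design_matrix <- function(records) {
  Xb <- stats::model.matrix(~ 0 + batch_farm, data = records)
  if (nlevels(records$ww_class) > 1) {
    Xw <- stats::model.matrix(~ ww_class, data = records)[, -1, drop = FALSE]
    Xb <- cbind(Xb, Xw)
  }
  Xb
}

# Empirical per-trait variances used to centre the priors.
empirical_trait_var <- function(records) {
  v <- c(AL = stats::var(records$adg_al, na.rm = TRUE),
         R = stats::var(records$adg_r, na.rm = TRUE),
         M = stats::var(records$y_m))
  v[!is.finite(v) | v <= 0] <- 1
  v
}

#' Fit the recursive structural equation model by Gibbs sampling
#'
#' Samples the joint posterior of the structural coefficients, the
#' litter/cage/genomic covariance matrices, the diagonal residual variances
#' and the location effects, under the missing-by-design phenotype pattern
#' (each animal records one growth trait). Structurally missing phenotypes
#' are data-augmented, which keeps every covariance full conditional balanced;
#' this is valid because the residual covariance is diagonal, the same
#' condition that makes the recursive model identifiable.
#'
#' @param data A `sem_dataset` (see [assemble_sem_dataset()]).
#' @param config A [sem_chain_config()].
#' @return A `sem_fit`: list with `draws` (tibble, one row per saved draw),
#'   `config`, `otu_id`, `trait_sd` (observed phenotypic SDs), `sizes`, `ess`
#'   for the structural coefficients, and optionally `b_draws`.
#' @export
fit_sem <- function(data, config = sem_chain_config()) {
  stopifnot(inherits(data, "sem_dataset"), inherits(config, "sem_chain_config"))
  rec <- data$records
  n <- nrow(rec)
  X <- sem_design_matrix(rec)

  if (is.null(data$G)) {
    eg <- list(vectors = diag(n), values = rep(1, n))
  } else {
    eg <- eigen(data$G, symmetric = TRUE)
    if (min(eg$values) <= 1e-10) {
      stop("GRM is not positive definite; blend identity in (compute_grm blend_weight)",
           call. = FALSE)
    }
  }

  v <- empirical_trait_var(rec)
  S0 <- diag(config$cov_scale_frac * v)
  res_scale <- config$res_scale_frac * v

  y_al <- rec$adg_al; y_r <- rec$adg_r
  miss_al <- as.integer(is.na(y_al)); miss_r <- as.integer(is.na(y_r))
  y_al[is.na(y_al)] <- 0; y_r[is.na(y_r)] <- 0

  set.seed(config$seed)
  res <- gibbs_sem_cpp(y_al, y_r, rec$y_m, miss_al, miss_r, X,
                       rec$litter - 1L, rec$cage - 1L,
                       eg$vectors, eg$values,
                       config$n_iter, config$burn_in, config$thin,
                       S0, S0, S0, config$nu0, res_scale, config$nu_e,
                       config$prior_var_b, config$prior_var_lambda,
                       config$save_effects, NULL, FALSE)
  draws <- tibble::as_tibble(as.data.frame(res$draws))
  names(draws) <- sem_draw_names()
  b_draws <- NULL
  if (config$save_effects) {
    b_draws <- tibble::as_tibble(as.data.frame(res$b_draws))
    names(b_draws) <- paste0("b_", rep(c("AL", "R", "M"), each = ncol(X)), "_",
                             rep(colnames(X), times = 3))
  }
  structure(list(
    draws = draws, b_draws = b_draws, config = config, otu_id = data$otu_id,
    trait_sd = c(AL = stats::sd(rec$adg_al, na.rm = TRUE),
                 R = stats::sd(rec$adg_r, na.rm = TRUE),
                 M = stats::sd(rec$y_m)),
    sizes = data$sizes,
    ess = c(lambda_AL = effective_sample_size(draws$lambda_AL),
            lambda_R = effective_sample_size(draws$lambda_R))),
    class = "sem_fit")
}

sem_draw_names <- function() {
  tri <- c("11", "21", "22", "31", "32", "33")
  c("lambda_AL", "lambda_R",
    paste0("L0_", tri), paste0("C0_", tri), paste0("G0_", tri),
    paste0("R0_", c("11", "22", "33")))
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("<sem_fit> OTU %s: %d saved draws (n = %d)\n",
              x$otu_id, nrow(x$draws), x$sizes[["n"]]))
  cat(sprintf("  lambda_AL: mean %.3f (ESS %.0f), lambda_R: mean %.3f (ESS %.0f)\n",
              mean(x$draws$lambda_AL), x$ess[["lambda_AL"]],
              mean(x$draws$lambda_R), x$ess[["lambda_R"]]))
  invisible(x)
}

#' Posterior summaries of a fitted model
#'
#' @param x A `sem_fit`.
#' @param hpd_prob HPD probability content.
#' @param ... Unused.
#' @return Tibble with one row per sampled parameter: posterior mean, median,
#'   SD, HPD bounds and effective sample size.
#' @export
tidy.sem_fit <- function(x, hpd_prob = 0.95, ...) {
  purrr::map_dfr(names(x$draws), function(nm) {
    v <- x$draws[[nm]]
    h <- hpd_interval(v, hpd_prob)
    tibble::tibble(term = nm, estimate = mean(v), median = stats::median(v),
                   std.error = stats::sd(v),
                   hpd.lower = h[["lower"]], hpd.upper = h[["upper"]],
                   ess = effective_sample_size(v))
  })
}

#' One-row summary of a fitted model
#' @param x A `sem_fit`.
#' @param ... Unused.
#' @return One-row tibble with chain sizes and structural-coefficient ESS.
#' @export
glance.sem_fit <- function(x, ...) {
  tibble::tibble(otu_id = x$otu_id, n_animals = x$sizes[["n"]],
                 n_draws = nrow(x$draws), n_iter = x$config$n_iter,
                 burn_in = x$config$burn_in, thin = x$config$thin,
                 ess_lambda_al = x$ess[["lambda_AL"]],
                 ess_lambda_r = x$ess[["lambda_R"]])
}

#' Posterior density plot of the structural coefficients
#' @param object A `sem_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sem_fit <- function(object, ...) {
  d <- object$draws |>
    dplyr::select("lambda_AL", "lambda_R") |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "coefficient")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, fill = .data$coefficient)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "structural coefficient (g/day per CSS unit)", y = "posterior density",
                  title = paste("OTU", object$otu_id)) +
    ggplot2::theme_minimal()
}

#' Autocorrelation-based effective sample size
#'
#' ESS = n / (1 + 2 sum of autocorrelations), truncated by Geyer's initial
#' positive sequence rule (stop when the sum of an even-odd lag pair turns
#' non-positive). A constant chain is degenerate: its ESS is reported as n
#' with a warning.
#'
#' @param x Numeric vector of draws (at least 10).
#' @return Effective sample size, clamped to `[1, length(x)]`.
#' @export
effective_sample_size <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10) stop("need at least 10 draws", call. = FALSE)
  if (stats::var(x) == 0) {
    warning("constant chain: effective sample size is degenerate", call. = FALSE)
    return(n)
  }
  rho <- stats::acf(x, lag.max = min(n - 1, 10 * ceiling(log10(n)) * 10),
                    plot = FALSE)$acf[-1]
  s <- 0
  k <- 1
  while (k <= length(rho) - 1) {
    pair <- rho[k] + rho[k + 1]
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, min(n, n / (1 + 2 * s)))
}

#' Reduced-model consistency check of a chain
#'
#' For a subsample of posterior draws, verifies the defining identity of the
#' reduced (multiple-trait animal model) form: every starred covariance
#' matrix computed by the scalar expansions must equal the explicit matrix
#' transform `(I - Lambda)^-1 theta0 (I - Lambda)^-T` entrywise. Any
#' discrepancy beyond numerical precision indicates an implementation defect.
#'
#' @param fit A `sem_fit`.
#' @param n_draws Number of draws to check (default 50, evenly spaced).
#' @return A tibble with the max absolute discrepancy per component matrix.
#' @export
reduced_model_check <- function(fit, n_draws = 50) {
  stopifnot(inherits(fit, "sem_fit"))
  d <- fit$draws
  idx <- unique(round(seq(1, nrow(d), length.out = min(n_draws, nrow(d)))))
  comp <- purrr::map_dfr(idx, function(i) {
    lam_al <- d$lambda_AL[i]; lam_r <- d$lambda_R[i]
    purrr::map_dfr(c("L0", "C0", "G0", "R0"), function(pref) {
      th <- draw_mat(d, pref, i)
      star <- transform_covariance(th, lam_al, lam_r)
      # scalar expansions of the same transform
      scal <- th
      scal[1, 1] <- genetic_variance_parts(th, lam_al, lam_r, "AL")[["total"]]
      scal[2, 2] <- genetic_variance_parts(th, lam_al, lam_r, "R")[["total"]]
      cv <- genetic_covariance_parts(th, lam_al, lam_r)
      scal[1, 2] <- scal[2, 1] <- cv$al_r[["total"]]
      scal[1, 3] <- scal[3, 1] <- cv$al_m[["total"]]
      scal[2, 3] <- scal[3, 2] <- cv$r_m[["total"]]
      tibble::tibble(component = pref, draw = i,
                     discrepancy = max(abs(star - scal)))
    })
  })
  comp |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(max_abs_discrepancy = max(.data$discrepancy), .groups = "drop")
}

#' Write a chain as a columnar TSV plus a JSON metadata sidecar
#' @param fit A `sem_fit`.
#' @param path Output TSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_chain <- function(fit, path) {
  stopifnot(inherits(fit, "sem_fit"))
  readr::write_tsv(fit$draws, path)
  meta <- list(otu_id = fit$otu_id, seed = fit$config$seed,
               n_iter = fit$config$n_iter, burn_in = fit$config$burn_in,
               thin = fit$config$thin, trait_sd = as.list(fit$trait_sd),
               sizes = as.list(fit$sizes))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
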