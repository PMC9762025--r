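#' Simulation truth for the recursive model
#'
#' Bundles the generative parameters of a synthetic population. The default
#' preset mirrors the scale of a rabbit growth study: ADG phenotypic SDs
#' around 5-6 g/day with moderate genetic correlation between the feeding
#' regimes, litter and cage variances a modest share of the total, an OTU
#' abundance on a unit-variance CSS-like scale with low-to-moderate
#' heritability, and structural coefficients in the observed range of a few
#' g/day per CSS unit.
#'
#' @param lambda_al,lambda_r Structural coefficients of the mediator on the
#'   two growth traits (default 0).
#' @param L0,C0,G0 Symmetric positive-definite 3x3 covariance matrices for
#'   litter, cage and genomic effects (trait order AL, R, M).
#' @param R0 Diagonal residual covariance (supplied as a 3-vector of
#'   variances).
#' @param b_batch Matrix `n_batches x 3` of batch-farm effects (g/day for the
#'   growth traits, CSS units for M); default spreads batches a few g/day.
#' @param b_ww 3-vector contrast of the small vs large weaning-weight class.
#' @return A `sim_truth` list.
#' @export
sim_truth <- function(lambda_al = 0, lambda_r = 0,
                      L0 = NULL, C0 = NULL, G0 = NULL, R0 = NULL,
                      b_batch = NULL, b_ww = c(-2, -2, 0)) {
  cov3 <- function(v, r12, r13, r23) {
    s <- sqrt(v)
    m <- diag(v)
    m[1, 2] <- m[2, 1] <- r12 * s[1] * s[2]
    m[1, 3] <- m[3, 1] <- r13 * s[1] * s[3]
    m[2, 3] <- m[3, 2] <- r23 * s[2] * s[3]
    m
  }
  # litter/cage covariances with the mediator default to zero: with at most
  # two animals per level they are not separable from the structural
  # coefficient, so a parameter-known testbed must not carry them
  if (is.null(L0)) L0 <- cov3(c(4, 3, 0.10), 0.4, 0, 0)
  if (is.null(C0)) C0 <- cov3(c(3, 3, 0.10), 0.4, 0, 0)
  if (is.null(G0)) G0 <- cov3(c(7, 5, 0.15), 0.59, 0.2, 0.2)
  if (is.null(R0)) R0 <- c(21, 17, 0.65)
  R0 <- as.numeric(R0)
  stopifnot(length(R0) == 3, all(R0 >= 0))
  for (m in list(L0, C0, G0)) {
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      stop("truth covariance matrices must be positive semi-definite", call. = FALSE)
    }
  }
  structure(list(lambda_al = lambda_al, lambda_r = lambda_r,
                 L0 = L0, C0 = C0, G0 = G0, R0 = R0,
                 b_batch = b_batch, b_ww = as.numeric(b_ww)),
            class = "sim_truth")
}

#' Simulate a parameter-known study population
#'
#' Generates genotypes, the genomic relationship matrix, litter/cage/genomic
#' random effects and the three traits in generative order: the mediator M
#' first, then each growth trait as its systematic part plus
#' `lambda * y_m` plus its own random effects and residual. Each animal is
#' then assigned a feeding regime at random (50/50) and the growth trait not
#' expressed under that regime is masked, reproducing the structural
#' missingness of the study design. Litters are placed so that no litter
#' contributes more than two animals to a cage.
#'
#' @param n_animals,n_litters,n_cages,n_batches Design sizes. Defaults mirror
#'   a cohort of ~400 animals in ~195 litters and ~189 cages over 5
#'   batch-farm levels.
#' @param n_snps SNPs used to build the genomic relationship matrix
#'   (binomial dosages with per-SNP allele frequencies Uniform(0.05, 0.5)).
#' @param truth A [sim_truth()].
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param grm `"genomic"` (simulate genotypes, VanRaden GRM) or `"identity"`
#'   (unrelated animals; use for very large populations where only the trait
#'   algebra is under study).
#' @param blend_weight Identity blend for the GRM (see [compute_grm()]).
#' @return List with `data` (a `sem_dataset`), `genotypes` (or `NULL`),
#'   `grm`, and `truth` (the input truth extended with the latent draws and
#'   the complete pre-masking phenotypes).
#' @export
simulate_population <- function(n_animals = 400, n_litters = 195,
                                n_cages = 189, n_batches = 5, n_snps = 1000,
                                truth = sim_truth(), seed = 1L,
                                grm = c("genomic", "identity"),
                                blend_weight = 0.01) {
  grm <- match.arg(grm)
  stopifnot(inherits(truth, "sim_truth"))
  stopifnot(n_litters <= n_animals, n_cages <= n_animals, n_batches >= 1)
  set.seed(seed)
  n <- n_animals

  # litters: balanced random assignment; cages: balanced random assignment
  # repaired so no litter contributes more than two animals to a cage
  litter <- sample(rep_len(seq_len(n_litters), n))
  cage <- assign_cages(litter, n_cages)

  batch <- sample(rep_len(seq_len(n_batches), n))
  ww <- sample(c("large", "small"), n, replace = TRUE)

  genotypes <- NULL
  ids <- sprintf("A%05d", seq_len(n))
  if (grm == "genomic") {
    p_snp <- stats::runif(n_snps, 0.05, 0.5)
    dos <- vapply(p_snp, function(p) stats::rbinom(n, 2, p), numeric(n))
    dimnames(dos) <- list(ids, sprintf("snp%05d", seq_len(n_snps)))
    genotypes <- genotype_matrix(dos)
    G <- compute_grm(genotypes, blend_weight = blend_weight)$values
  } else {
    G <- NULL # unrelated animals; never materialized
  }

  rmat <- function(cov, n_levels) {
    # n_levels x 3 with rows iid N(0, cov); eigen factor so that singular
    # (degenerate) truth matrices are handled exactly
    e <- eigen(cov, symmetric = TRUE)
    f <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
    matrix(stats::rnorm(n_levels * 3), n_levels, 3) %*% f
  }
  l_eff <- rmat(truth$L0, n_litters)
  c_eff <- rmat(truth$C0, n_cages)
  # u ~ N(0, G0 (x) G): cov(vec(U)) with column stacking is G0 (x) G
  u_eff <- rmat(truth$G0, n)
  if (!is.null(G)) u_eff <- t(chol(G)) %*% u_eff
  e_eff <- matrix(stats::rnorm(n * 3), n, 3) %*% diag(sqrt(truth$R0))

  b_batch <- truth$b_batch
  if (is.null(b_batch)) {
    b_batch <- cbind(seq(50, 58, length.out = n_batches),
                     seq(35, 42, length.out = n_batches),
                     rep(0.5, n_batches))
  }
  stopifnot(nrow(b_batch) == n_batches, ncol(b_batch) == 3)
  fixed <- b_batch[batch, , drop = FALSE] +
    outer(as.numeric(ww == "small"), truth$b_ww)

  y_m <- fixed[, 3] + l_eff[litter, 3] + c_eff[cage, 3] + u_eff[, 3] + e_eff[, 3]
  y_al <- fixed[, 1] + truth$lambda_al * y_m +
    l_eff[litter, 1] + c_eff[cage, 1] + u_eff[, 1] + e_eff[, 1]
  y_r <- fixed[, 2] + truth$lambda_r * y_m +
    l_eff[litter, 2] + c_eff[cage, 2] + u_eff[, 2] + e_eff[, 2]

  regime <- sample(c("AL", "R"), n, replace = TRUE)
  records <- tibble::tibble(
    animal_id = ids,
    regime = regime,
    adg_al = ifelse(regime == "AL", y_al, NA_real_),
    adg_r = ifelse(regime == "R", y_r, NA_real_),
    y_m = y_m,
    batch_farm = paste0("B", batch),
    ww_class = ww,
    litter_id = paste0("L", litter),
    cage_id = paste0("C", cage),
    litter = litter,
    cage = cage)
  data <- sem_dataset(records, G, otu_id = "sim_OTU", scale = "CSS")

  truth_out <- truth
  truth_out$seed <- seed
  truth_out$l_eff <- l_eff; truth_out$c_eff <- c_eff
  truth_out$u_eff <- u_eff; truth_out$e_eff <- e_eff
  truth_out$y_al_complete <- y_al; truth_out$y_r_complete <- y_r
  truth_out$y_m <- y_m
  truth_out$b_batch <- b_batch
  list(data = data, genotypes = genotypes, grm = G, truth = truth_out)
}

# Balanced random cage assignment, repaired so that no litter contributes
# more than two animals to any cage.
assign_cages <- function(litter, n_cages) {
  n <- length(litter)
  cage <- integer(n)
  cage[sample.int(n)] <- rep_len(seq_len(n_cages), n)
  repeat {
    key <- paste(litter, cage)
    cnt <- table(key)
    bad <- names(cnt)[cnt > 2]
    if (!length(bad)) break
    offenders <- which(key %in% bad)
    move <- unlist(lapply(split(offenders, key[offenders]), function(ix) ix[-(1:2)]))
    cage[move] <- sample.int(n_cages, length(move), replace = TRUE)
  }
  cage
}

#' Phenotypic covariance implied by the generator's parameters
#'
#' The reduced-model identity: across animals (identity relationships), the
#' covariance of the complete traits (y_AL, y_R, y_M) net of fixed effects is
#' the sum of the starred (reduced-model) litter, cage, genomic and residual
#' matrices. Used to validate the generator against its own algebra.
#'
#' @param truth A [sim_truth()].
#' @return Symmetric 3x3 matrix.
#' @export
implied_phenotype_covariance <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  th <- truth$L0 + truth$C0 + truth$G0 + diag(truth$R0)
  transform_covariance(th, truth$lambda_al, truth$lambda_r)
}

#' Score posterior recovery of known simulation parameters
#'
#' @param truth The `truth` element returned by [simulate_population()].
#' @param fit A `sem_fit` on the corresponding dataset.
#' @param hpd_prob HPD probability content.
#' @return Tibble with one row per parameter: truth, posterior mean, bias,
#'   HPD bounds and whether the truth is covered.
#' @export
score_recovery <- function(truth, fit, hpd_prob = 0.95) {
  stopifnot(inherits(fit, "sem_fit"))
  d <- fit$draws
  tri <- function(m) c(m[1, 1], m[2, 1], m[2, 2], m[3, 1], m[3, 2], m[3, 3])
  tru <- c(lambda_AL = truth$lambda_al, lambda_R = truth$lambda_r,
           stats::setNames(tri(truth$L0), paste0("L0_", c("11","21","22","31","32","33"))),
           stats::setNames(tri(truth$C0), paste0("C0_", c("11","21","22","31","32","33"))),
           stats::setNames(tri(truth$G0), paste0("G0_", c("11","21","22","31","32","33"))),
           stats::setNames(truth$R0, paste0("R0_", c("11", "22", "33"))))
  purrr::map_dfr(names(tru), function(nm) {
    v <- d[[nm]]
    h <- hpd_interval(v, hpd_prob)
    tibble::tibble(term = nm, truth = tru[[nm]], estimate = mean(v),
                   bias = mean(v) - tru[[nm]],
                   hpd.lower = h[["lower"]], hpd.upper = h[["upper"]],
                   covered = tru[[nm]] >= h[["lower"]] & tru[[nm]] <= h[["upper"]])
  })
}
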