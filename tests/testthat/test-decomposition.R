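test_that("transform_covariance reduces to the identity at lambda = 0", {
  set.seed(10)
  th <- random_pd3()
  expect_equal(transform_covariance(th, 0, 0), (th + t(th)) / 2)
})

test_that("transform_covariance matches the explicit matrix product", {
  # diag(1,1,1), lambda_AL = 2, lambda_R = 0: entry (1,1) = 1 + 0 + 4 = 5
  out <- transform_covariance(diag(3), 2, 0)
  expect_equal(out[1, 1], 5)

  set.seed(11)
  for (i in 1:20) {
    th <- random_pd3()
    lal <- rnorm(1); lr <- rnorm(1)
    B <- solve(diag(3) - lambda_matrix(lal, lr))
    expect_equal(transform_covariance(th, lal, lr), B %*% th %*% t(B),
                 ignore_attr = TRUE)
  }
})

test_that("the mediator variance is invariant under the transform", {
  set.seed(12)
  for (i in 1:10) {
    th <- random_pd3()
    lal <- rnorm(1, 0, 2); lr <- rnorm(1, 0, 2)
    expect_equal(transform_covariance(th, lal, lr)[3, 3], th[3, 3])
  }
})

test_that("transform preserves symmetry and positive definiteness", {
  set.seed(13)
  for (i in 1:25) {
    th <- random_pd3()
    out <- transform_covariance(th, rnorm(1, 0, 3), rnorm(1, 0, 3))
    expect_identical(out, t(out))
    expect_gt(min(eigen(out, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("genetic variance parts: direct + indirect = total, exact values", {
  g0 <- diag(3)
  expect_equal(genetic_variance_parts(g0, 0, 0, "AL")[["indirect"]], 0)

  # sigma2 = 1, lambda = 0.5, cov = 0.2, sigma2_M = 1 -> total 1.45
  g1 <- diag(3); g1[1, 3] <- g1[3, 1] <- 0.2
  v <- genetic_variance_parts(g1, 0.5, 0, "AL")
  expect_equal(v[["total"]], 1.45)
  expect_equal(v[["total"]], v[["direct"]] + v[["indirect"]])

  # negative mediation with small lambda: indirect < 0, total > 0
  g2 <- diag(3); g2[1, 3] <- g2[3, 1] <- -0.3
  v2 <- genetic_variance_parts(g2, 0.1, 0, "AL")
  expect_equal(v2[["indirect"]], 2 * 0.1 * -0.3 + 0.01)
  expect_equal(v2[["indirect"]], -0.05)
  expect_gt(v2[["total"]], 0)
})

test_that("scalar expansions equal the matrix transform entrywise", {
  set.seed(14)
  for (i in 1:50) {
    g0 <- random_pd3()
    lal <- rnorm(1, 0, 2); lr <- rnorm(1, 0, 2)
    star <- transform_covariance(g0, lal, lr)
    expect_equal(genetic_variance_parts(g0, lal, lr, "AL")[["total"]], star[1, 1])
    expect_equal(genetic_variance_parts(g0, lal, lr, "R")[["total"]], star[2, 2])
    cv <- genetic_covariance_parts(g0, lal, lr)
    expect_equal(cv$al_r[["total"]], star[1, 2])
    expect_equal(cv$al_m[["total"]], star[1, 3])
    expect_equal(cv$r_m[["total"]], star[2, 3])
  }
})

test_that("a tuned lambda can null the total mediator covariance", {
  set.seed(15)
  g0 <- random_pd3()
  lal <- -g0[1, 3] / g0[3, 3]
  cv <- genetic_covariance_parts(g0, lal, 0)
  expect_equal(cv$al_m[["total"]], 0)
  # lambda = 0: totals equal directs
  cv0 <- genetic_covariance_parts(g0, 0, 0)
  expect_equal(cv0$al_m[["total"]], cv0$al_m[["direct"]])
  expect_equal(cv0$al_r[["total"]], cv0$al_r[["direct"]])
})

test_that("heritability uses the right numerator and denominator", {
  z <- matrix(0, 3, 3)
  g <- diag(c(2, 1, 1))
  expect_equal(heritability(z, z, g, z, trait = "AL"), 1)

  l <- diag(c(1, 1, 1)); c0 <- diag(c(1, 1, 1)); r <- diag(c(1, 1, 1))
  expect_equal(heritability(l, c0, diag(3), r, trait = "AL"), 0.25)

  # total mode equals the transform-everything oracle
  set.seed(16)
  l0 <- random_pd3(); cc <- random_pd3(); g0 <- random_pd3(); r0 <- diag(runif(3, 0.5, 2))
  lal <- 0.7; lr <- -1.2
  star <- function(m) transform_covariance(m, lal, lr)
  h_oracle <- star(g0)[2, 2] /
    (star(g0)[2, 2] + star(l0)[2, 2] + star(cc)[2, 2] + star(r0)[2, 2])
  expect_equal(heritability(l0, cc, g0, r0, lal, lr, "R", "total"), h_oracle)

  expect_error(heritability(z, z, z, z, trait = "AL"), "non-positive")
})

test_that("standardized effects reproduce the published worked examples", {
  expect_equal(round(standardize_effect(-1.929, 5.27), 3), -0.366)
  expect_equal(round(standardize_effect(1.859, 5.27), 3), 0.353)
  expect_equal(standardize_effect(0, 3.3), 0)
  expect_error(standardize_effect(1, 0), "positive")
})

test_that("hpd_interval is the exhaustive shortest-window solution", {
  # constant draws: zero width
  expect_equal(unname(hpd_interval(rep(2.5, 30))), c(2.5, 2.5))

  # draws 1..100 at prob 0.95: all width-94 windows tie; lowest start wins
  expect_equal(unname(hpd_interval(1:100, 0.95)), c(1, 95))

  # random draws against an independent exhaustive window scan
  set.seed(17)
  for (i in 1:10) {
    x <- rgamma(200, shape = 2) # skewed, so HPD != equal-tail
    xs <- sort(x)
    m <- ceiling(0.9 * 200)
    widths <- vapply(1:(200 - m + 1), function(j) xs[j + m - 1] - xs[j], numeric(1))
    j <- which.min(widths)
    expect_equal(unname(hpd_interval(x, 0.9)), c(xs[j], xs[j + m - 1]))
  }

  expect_error(hpd_interval(1:10), "at least 20")
})

test_that("hpd_interval approaches normal quantiles and contains the median", {
  set.seed(18)
  x <- rnorm(1e5)
  h <- hpd_interval(x, 0.95)
  expect_equal(h[["lower"]], -1.96, tolerance = 0.05)
  expect_equal(h[["upper"]], 1.96, tolerance = 0.05)

  for (i in 1:5) {
    y <- rlnorm(500)
    h2 <- hpd_interval(y, 0.8)
    expect_true(h2[["lower"]] <= median(y) && median(y) <= h2[["upper"]])
  }
})

test_that("significance is HPD zero-exclusion; relevance is a magnitude call", {
  expect_true(is_significant(seq(0.1, 5, length.out = 50)))
  set.seed(19)
  expect_false(is_significant(rnorm(2000)))
  expect_true(is_significant(rnorm(2000, mean = 3)))

  expect_true(classify_relevant(-0.322))
  expect_false(classify_relevant(0.19))
  expect_true(classify_relevant(0.2)) # boundary included
})

test_that("posterior decomposition satisfies the exact per-draw identities", {
  fit <- shared_fit()
  dec <- decompose_posterior(fit)
  expect_equal(nrow(dec), 2)
  expect_equal(dec$gvar_total, dec$gvar_direct + dec$gvar_indirect)
  expect_equal(dec$gcov_m_total, dec$gcov_m_direct + dec$gcov_m_indirect)
  alr <- attr(dec, "gcov_al_r")
  expect_equal(alr[["total"]], alr[["direct"]] + alr[["mediated"]])
  expect_true(all(dec$h2_direct >= 0 & dec$h2_direct <= 1))
  expect_true(all(dec$h2_total >= 0 & dec$h2_total <= 1))
  expect_equal(dec$std_effect,
               dec$lambda_mean / unname(fit$trait_sd[c("AL", "R")]))
})
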