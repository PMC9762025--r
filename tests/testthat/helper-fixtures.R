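# Shared fixtures built in code.

toy_counts <- function() {
  # 10 samples x 3 OTUs: A detected in 6 samples (sum 600), B in 1 (sum 1),
  # C never
  m <- matrix(0, 10, 3, dimnames = list(paste0("s", 1:10), c("A", "B", "C")))
  m[1:6, "A"] <- 100
  m[7, "B"] <- 1
  m
}

random_pd3 <- function() {
  a <- matrix(stats::rnorm(9), 3, 3)
  crossprod(a) + diag(0.1, 3)
}

# One small fitted model shared by the tests that only need a valid sem_fit.
shared_fit <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      tr <- sim_truth(lambda_al = 1, lambda_r = -0.5)
      sim <- simulate_population(200, 96, 94, n_snps = 300, truth = tr, seed = 321)
      val <<- fit_sem(sim$data,
                      sem_chain_config(n_iter = 1200, burn_in = 400, thin = 2,
                                       seed = 11))
    }
    val
  }
})
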