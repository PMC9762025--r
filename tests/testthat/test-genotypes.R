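test_that("snp_qc applies the four criteria sequentially", {
  # 5 animals x 4 SNPs: animal 5 missing-heavy; snp4 is X-linked
  dos <- rbind(a1 = c(0, 1, 2, 0),
               a2 = c(1, 1, 2, 1),
               a3 = c(0, 1, 2, 0),
               a4 = c(1, 0, 2, 1),
               a5 = c(NA, NA, NA, 0))
  colnames(dos) <- paste0("snp", 1:4)
  meta <- tibble::tibble(snp_id = colnames(dos),
                         chromosome = c("1", "2", "3", "X"),
                         position = c(100, 200, 300, 400))
  g <- genotype_matrix(dos, meta)

  # independent tally oracle
  keep_ind <- rowMeans(!is.na(dos)) > 0.9
  d2 <- dos[keep_ind, ]
  p <- colMeans(d2, na.rm = TRUE) / 2
  keep_snp <- colMeans(!is.na(d2)) > 0.95 & pmin(p, 1 - p) > 0.05 &
    meta$chromosome %in% as.character(1:30)

  out <- snp_qc(g)
  expect_identical(rownames(out$dosages), rownames(dos)[keep_ind])
  expect_identical(colnames(out$dosages), colnames(dos)[keep_snp])
  # snp3 is monomorphic (MAF 0) and snp4 X-linked: both must be gone
  expect_false(any(c("snp3", "snp4") %in% colnames(out$dosages)))
})

test_that("snp_qc removes SNPs at or below the MAF threshold", {
  set.seed(1)
  n <- 50
  dos <- cbind(low_maf = rbinom(n, 2, 0.04), ok = rbinom(n, 2, 0.5))
  rownames(dos) <- paste0("a", 1:n)
  g <- genotype_matrix(dos)
  maf <- min(mean(dos[, 1]) / 2, 1 - mean(dos[, 1]) / 2)
  out <- snp_qc(g, maf_min = 0.05, autosomal_only = FALSE)
  expect_identical("low_maf" %in% colnames(out$dosages), maf > 0.05)
  expect_true("ok" %in% colnames(out$dosages))
})

test_that("snp_qc with null thresholds is the identity on complete data", {
  set.seed(2)
  dos <- matrix(rbinom(40, 2, 0.5), 10, 4,
                dimnames = list(paste0("a", 1:10), paste0("s", 1:4)))
  g <- genotype_matrix(dos)
  out <- snp_qc(g, ind_call_min = 0, snp_call_min = 0, maf_min = 0,
                autosomal_only = FALSE)
  expect_identical(out$dosages, g$dosages)

  expect_error(snp_qc(g, maf_min = 1, autosomal_only = FALSE), "all 4 SNPs removed")
})

test_that("impute_missing fills per-SNP means and leaves complete data alone", {
  dos <- rbind(a1 = c(0, 2, 1), a2 = c(2, 0, 1), a3 = c(NA, 1, 1), a4 = c(0, NA, NA))
  colnames(dos) <- paste0("s", 1:3)
  g <- impute_missing(genotype_matrix(dos))
  expect_equal(g$dosages["a3", "s1"], mean(c(0, 2, 0)))
  expect_equal(g$dosages["a4", "s2"], mean(c(2, 0, 1)))
  expect_equal(g$dosages["a4", "s3"], 1)

  complete <- genotype_matrix(dos[1:2, ])
  expect_identical(impute_missing(complete)$dosages, complete$dosages)

  all_na <- rbind(a1 = c(0, NA), a2 = c(1, NA))
  colnames(all_na) <- c("ok", "gone")
  expect_error(impute_missing(genotype_matrix(all_na)), "no observed genotypes")
})

test_that("compute_grm matches the explicit VanRaden product on a toy matrix", {
  dos <- rbind(a1 = c(0, 2), a2 = c(1, 1), a3 = c(2, 0))
  colnames(dos) <- c("s1", "s2")
  p <- colMeans(dos) / 2
  W <- sweep(dos, 2, 2 * p)
  G_oracle <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  g <- compute_grm(genotype_matrix(dos), blend_weight = 0)
  expect_equal(unname(g$values), unname(G_oracle))

  # centered columns sum to zero by construction
  expect_equal(colSums(W), c(s1 = 0, s2 = 0))
})

test_that("identical genotypes give equal diagonal and off-diagonal entries", {
  set.seed(3)
  base <- rbinom(20, 2, 0.4)
  dos <- rbind(a1 = base, a2 = base, a3 = rbinom(20, 2, 0.4))
  colnames(dos) <- paste0("s", 1:20)
  g <- compute_grm(genotype_matrix(dos), blend_weight = 0)
  expect_equal(g$values["a1", "a2"], g$values["a1", "a1"])
  expect_equal(g$values["a1", "a1"], g$values["a2", "a2"])
})

test_that("blended GRM is symmetric positive definite", {
  set.seed(4)
  dos <- matrix(rbinom(60 * 120, 2, rep(runif(120, 0.1, 0.5), each = 60)), 60, 120,
                dimnames = list(paste0("a", 1:60), paste0("s", 1:120)))
  g <- compute_grm(genotype_matrix(dos), blend_weight = 0.01)
  expect_equal(g$values, t(g$values))
  expect_silent(chol(g$values)) # factorization success is the PD check

  mono <- matrix(2, 5, 3, dimnames = list(paste0("a", 1:5), paste0("s", 1:3)))
  expect_error(compute_grm(genotype_matrix(mono)), "monomorphic")
})

test_that("PLINK bed/bim/fam round-trips dosages, ids and metadata", {
  set.seed(5)
  dos <- matrix(rbinom(9 * 7, 2, 0.4), 9, 7,
                dimnames = list(paste0("ind", 1:9), paste0("rs", 1:7)))
  dos[2, 3] <- NA
  dos[5, 1] <- NA
  meta <- tibble::tibble(snp_id = colnames(dos),
                         chromosome = c("1", "2", "X", "3", "4", "5", "0"),
                         position = c(1:6 * 1000, 0))
  g <- genotype_matrix(dos, meta)
  prefix <- tempfile()
  write_plink(g, prefix)
  rd <- read_plink(prefix)
  expect_equal(rd$dosages, g$dosages)
  expect_equal(rd$snp_meta$chromosome, meta$chromosome)
  expect_equal(rd$snp_meta$is_autosomal, g$snp_meta$is_autosomal)
  # non-autosomal flags: X chromosome and unknown position
  expect_false(rd$snp_meta$is_autosomal[3])
  expect_false(rd$snp_meta$is_autosomal[7])
  unlink(paste0(prefix, c(".bed", ".bim", ".fam")))
})

test_that("GRM TSV round trip preserves values and ids", {
  set.seed(6)
  dos <- matrix(rbinom(5 * 30, 2, 0.3), 5, 30,
                dimnames = list(paste0("a", 1:5), paste0("s", 1:30)))
  g <- compute_grm(genotype_matrix(dos))
  f <- tempfile(fileext = ".tsv")
  write_grm(g, f)
  rd <- read_grm(f)
  expect_equal(rd$values, g$values, tolerance = 1e-12)
  unlink(f)
})
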