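test_that("filter_otus keeps exactly the OTUs passing both thresholds", {
  x <- otu_counts(toy_counts())

  # independent per-column scan oracle
  oracle <- function(m, prev, ab) {
    keep <- logical(ncol(m))
    for (j in seq_len(ncol(m))) {
      keep[j] <- mean(m[, j] > 0) >= prev && sum(m[, j]) / sum(m) >= ab
    }
    colnames(m)[keep]
  }
  out <- filter_otus(x, prevalence_min = 0.5, abundance_min = 0.01)
  expect_identical(colnames(out$counts), oracle(toy_counts(), 0.5, 0.01))
  expect_identical(colnames(out$counts), "A")
  expect_identical(rownames(out$counts), rownames(x$counts))

  # all-zero column removed under any positive thresholds
  out2 <- filter_otus(x, prevalence_min = 1e-9, abundance_min = 1e-9)
  expect_false("C" %in% colnames(out2$counts))
})

test_that("filter_otus retains values exactly at the thresholds", {
  # 1 of 20 samples = 5% detection: the removal rule is strictly 'less than'
  m <- matrix(0, 20, 2, dimnames = list(paste0("s", 1:20), c("rare", "common")))
  m[1, "rare"] <- 1000
  m[, "common"] <- 50
  out <- filter_otus(otu_counts(m), prevalence_min = 0.05, abundance_min = 1e-4)
  expect_true("rare" %in% colnames(out$counts))
})

test_that("filter_otus is idempotent and errors on degenerate input", {
  x <- otu_counts(toy_counts())
  once <- filter_otus(x, 0.5, 0.01)
  twice <- filter_otus(once, 0.5, 0.01)
  expect_identical(once$counts, twice$counts)
  expect_error(filter_otus(x, 1, 0.9), "all 3 OTUs removed")
})

test_that("css_normalize matches the hand-evaluated cumulative-sum rule", {
  m <- matrix(c(2, 4, 2, 4), 2, 2,
              dimnames = list(c("s1", "s2"), c("o1", "o2")))
  nt <- css_normalize(otu_counts(m), quantile = 0.5)
  # sample 1: positive counts (2,2), median cutoff 2, s = 2+2 = 4
  # sample 2: (4,4) -> s = 8; reference = median(4,8) = 6
  expect_equal(unname(nt$scaling_factors), c(4, 8))
  expect_equal(nt$reference_scale, 6)
  expect_equal(unname(nt$values), matrix(3, 2, 2))
})

test_that("proportional samples normalize identically and symmetry holds", {
  set.seed(42)
  base <- rpois(30, 20)
  m <- rbind(s1 = base, s2 = 3 * base, s3 = 7 * base)
  colnames(m) <- paste0("o", seq_len(ncol(m)))
  nt <- css_normalize(otu_counts(m), quantile = 0.5)
  expect_equal(nt$values["s1", ], nt$values["s2", ])
  expect_equal(nt$values["s1", ], nt$values["s3", ])

  # identical count vectors across samples: values equal the counts rescaled
  m2 <- rbind(a = base, b = base)
  colnames(m2) <- paste0("o", seq_len(ncol(m2)))
  nt2 <- css_normalize(otu_counts(m2), quantile = 0.5)
  expect_equal(nt2$values["a", ], nt2$values["b", ])
})

test_that("css_normalize handles single-OTU tables, log2 and zero factors", {
  m <- matrix(c(5, 10, 20), 3, 1, dimnames = list(paste0("s", 1:3), "only"))
  nt <- css_normalize(otu_counts(m))
  expect_equal(unname(nt$values[, 1]), rep(nt$reference_scale, 3))

  ntl <- css_normalize(otu_counts(m), log2_transform = TRUE)
  expect_equal(unname(ntl$values[, 1]), rep(log2(nt$reference_scale + 1), 3))

  m0 <- matrix(c(1, 0), 2, 1, dimnames = list(c("ok", "empty"), "o"))
  expect_error(css_normalize(otu_counts(m0)), "empty")
})

test_that("compute_adg is the within-animal OLS slope of weight on age", {
  w <- tibble::tibble(animal_id = "a1", age_days = c(32, 39, 46, 53),
                      weight_g = 100 + 50 * c(32, 39, 46, 53))
  expect_equal(compute_adg(w)$adg, 50)

  w2 <- tibble::tibble(animal_id = "a2", age_days = c(32, 66),
                       weight_g = c(700, 2400))
  expect_equal(compute_adg(w2)$adg, (2400 - 700) / (66 - 32))

  # noisy series against the closed-form OLS oracle
  set.seed(7)
  age <- c(32, 39, 46, 53)
  wt <- 150 + 47 * age + rnorm(4, 0, 30)
  slope_oracle <- sum((age - mean(age)) * (wt - mean(wt))) / sum((age - mean(age))^2)
  w3 <- tibble::tibble(animal_id = "a3", age_days = age, weight_g = wt)
  expect_equal(compute_adg(w3)$adg, slope_oracle)
})

test_that("compute_adg slope invariances and error conditions", {
  set.seed(8)
  age <- c(30, 40, 50, 60)
  wt <- 200 + 30 * age + rnorm(4, 0, 10)
  base <- compute_adg(tibble::tibble(animal_id = "x", age_days = age, weight_g = wt))$adg
  shifted <- compute_adg(tibble::tibble(animal_id = "x", age_days = age + 11,
                                        weight_g = wt))$adg
  scaled <- compute_adg(tibble::tibble(animal_id = "x", age_days = age,
                                       weight_g = 2.5 * wt))$adg
  expect_equal(shifted, base)
  expect_equal(scaled, 2.5 * base)

  expect_error(compute_adg(tibble::tibble(animal_id = "y", age_days = c(40, 40),
                                          weight_g = c(1, 2))), "distinct ages")
  expect_error(compute_adg(tibble::tibble(animal_id = "z", age_days = 40,
                                          weight_g = 500)), "at least 2")
})

test_that("TSV round trip preserves the count table in both orientations", {
  set.seed(5)
  m <- matrix(rpois(4 * 12, 8), 4, 12,
              dimnames = list(paste0("s", 1:4), paste0("otu", 1:12)))
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(otu_id = colnames(m), t(m), check.names = FALSE)
  utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  rd <- read_otu_counts(f, orientation = "otus_x_samples")
  expect_equal(rd$counts, m)
  # auto-detect: the longer margin is taken as the OTU margin
  rd2 <- read_otu_counts(f, orientation = "auto")
  expect_equal(rd2$counts, m)
  unlink(f)
})

test_that("BIOM input round-trips through the biomformat reader", {
  m <- toy_counts()[, 1:2] # biom drops all-zero rows ambiguity; keep detected OTUs
  b <- biomformat::make_biom(t(m))
  f <- tempfile(fileext = ".biom")
  biomformat::write_biom(b, f)
  rd <- read_biom_counts(f)
  expect_equal(rd$counts[rownames(m), colnames(m)], m)
  unlink(f)
})

test_that("phenotype validation enforces the one-trait-per-animal design", {
  p <- tibble::tibble(
    animal_id = paste0("a", 1:4), regime = c("AL", "AL", "R", "R"),
    adg_al = c(50, 52, NA, NA), adg_r = c(NA, NA, 39, 41),
    batch_farm = "B1", ww_class = c("large", "small", "large", "small"),
    litter_id = c("L1", "L1", "L2", "L2"), cage_id = c("C1", "C2", "C1", "C2"))
  expect_silent(validate_phenotypes(p))

  bad <- p
  bad$adg_r[1] <- 40 # AL animal with both traits observed
  expect_error(validate_phenotypes(bad), "one observed, one missing")

  crowded <- p
  crowded$cage_id <- "C1"
  crowded$litter_id <- "L1"
  expect_warning(validate_phenotypes(crowded), "more than 2 animals")
})

test_that("assemble_sem_dataset joins and aligns records with the GRM", {
  p <- tibble::tibble(
    animal_id = paste0("a", 1:6), regime = rep(c("AL", "R"), 3),
    adg_al = ifelse(rep(c(TRUE, FALSE), 3), 50 + 1:6, NA),
    adg_r = ifelse(rep(c(FALSE, TRUE), 3), 38 + 1:6, NA),
    batch_farm = rep(c("B1", "B2"), each = 3),
    ww_class = rep(c("large", "small"), 3),
    litter_id = rep(c("L1", "L2", "L3"), each = 2),
    cage_id = rep(c("C1", "C2", "C3"), 2))
  m <- matrix(rpois(6 * 2, 30), 6, 2,
              dimnames = list(paste0("a", 1:6), c("otuX", "otuY")))
  nt <- css_normalize(otu_counts(m))
  G <- diag(6)
  # GRM ordering deliberately scrambled relative to the phenotype table
  ord <- c("a3", "a1", "a6", "a2", "a5", "a4")
  dimnames(G) <- list(ord, ord)
  ds <- assemble_sem_dataset(p, nt, "otuX", G)
  expect_s3_class(ds, "sem_dataset")
  expect_identical(ds$records$animal_id, ord)
  # hand-aligned join: record for a3 carries a3's abundance and phenotypes
  expect_equal(ds$records$y_m[1], nt$values["a3", "otuX"])
  expect_equal(ds$records$adg_al[1], 53)
  expect_true(is.na(ds$records$adg_r[1]))

  # disjoint id sets must fail loudly, naming the missing animals
  G2 <- diag(6)
  dimnames(G2) <- list(paste0("z", 1:6), paste0("z", 1:6))
  expect_error(assemble_sem_dataset(p, nt, "otuX", G2), "unmatched animal ids")
  expect_error(assemble_sem_dataset(p, nt, "nope", G), "not found")
})
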