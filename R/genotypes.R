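#' Construct a genotype matrix
#'
#' Container for SNP dosages (minor-allele counts 0/1/2, `NA` for missing),
#' animals in rows and SNPs in columns, with per-SNP metadata used by
#' [snp_qc()].
#'
#' @param dosages Numeric matrix animals x SNPs with values in \{0, 1, 2, NA\},
#'   animal ids as rownames and SNP ids as colnames.
#' @param snp_meta Data frame with columns `snp_id`, `chromosome`, `position`;
#'   a SNP is autosomal when its chromosome is a positive integer label and
#'   its position is known (> 0).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snp_meta = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages))) stop("dosages must have animal ids as rownames", call. = FALSE)
  if (is.null(colnames(dosages))) stop("dosages must have SNP ids as colnames", call. = FALSE)
  if (anyDuplicated(rownames(dosages))) stop("duplicated animal ids", call. = FALSE)
  if (anyDuplicated(colnames(dosages))) stop("duplicated SNP ids", call. = FALSE)
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  storage.mode(dosages) <- "double"
  if (is.null(snp_meta)) {
    snp_meta <- tibble::tibble(snp_id = colnames(dosages),
                               chromosome = "1", position = seq_len(ncol(dosages)))
  }
  snp_meta <- tibble::as_tibble(snp_meta)
  stopifnot(all(c("snp_id", "chromosome", "position") %in% names(snp_meta)))
  if (!identical(as.character(snp_meta$snp_id), colnames(dosages))) {
    snp_meta <- snp_meta[match(colnames(dosages), snp_meta$snp_id), , drop = FALSE]
    if (anyNA(snp_meta$snp_id)) stop("snp_meta does not cover all SNPs", call. = FALSE)
  }
  chr <- as.character(snp_meta$chromosome)
  numeric_chr <- grepl("^[0-9]+$", chr)
  chr_num <- rep(0, length(chr))
  chr_num[numeric_chr] <- as.numeric(chr[numeric_chr])
  snp_meta$is_autosomal <- numeric_chr & chr_num > 0 &
    !is.na(snp_meta$position) & snp_meta$position > 0
  structure(list(dosages = dosages, snp_meta = snp_meta), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d animals x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages), 100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read PLINK bed/bim/fam genotypes
#'
#' Minimal reader for the binary PLINK 1 format (SNP-major bed). Dosages count
#' the A1 allele of the bim file (PLINK convention: usually the minor allele).
#'
#' @param prefix Path prefix; `<prefix>.bed`, `.bim`, `.fam` must exist.
#' @return A [genotype_matrix].
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim"); fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
  fam_df <- utils::read.table(fam, stringsAsFactors = FALSE)
  bim_df <- utils::read.table(bim, stringsAsFactors = FALSE)
  n <- nrow(fam_df); p <- nrow(bim_df)
  ids <- as.character(fam_df[[2]])
  con <- file(bed, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", n = 3)
  if (!identical(as.integer(magic), c(108L, 27L, 1L))) {
    stop("not a SNP-major PLINK bed file: ", bed, call. = FALSE)
  }
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(con, "raw", n = bytes_per_snp * p)
  if (length(raw) < bytes_per_snp * p) stop("truncated bed file", call. = FALSE)
  # 2-bit codes per individual: 00 hom A1 (dosage 2), 10 het (1), 11 hom A2 (0), 01 missing
  codes <- matrix(0L, nrow = 4 * bytes_per_snp, ncol = p)
  ints <- as.integer(raw)
  dim(ints) <- c(bytes_per_snp, p)
  for (shift in 0:3) {
    codes[seq(shift + 1, by = 4, length.out = bytes_per_snp), ] <- ints %/% 4L^shift %% 4L
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  lookup <- c(2, NA, 1, 0) # index by code + 1
  dos <- matrix(lookup[codes + 1L], nrow = n, ncol = p,
                dimnames = list(ids, as.character(bim_df[[2]])))
  genotype_matrix(dos, snp_meta = tibble::tibble(
    snp_id = as.character(bim_df[[2]]),
    chromosome = as.character(bim_df[[1]]),
    position = as.numeric(bim_df[[4]])))
}

#' Write PLINK bed/bim/fam genotypes
#'
#' Inverse of [read_plink()]; used by the synthetic generator so simulated
#' data exercise the same input path as real data.
#'
#' @param g A [genotype_matrix] (missing dosages allowed).
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  dos <- g$dosages
  n <- nrow(dos); p <- ncol(dos)
  fam <- data.frame(fid = rownames(dos), iid = rownames(dos),
                    pat = 0, mat = 0, sex = 0, phe = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  bim <- data.frame(chr = g$snp_meta$chromosome, id = g$snp_meta$snp_id,
                    cm = 0, pos = g$snp_meta$position, a1 = "A", a2 = "B")
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  code <- matrix(3L, nrow = 4 * ceiling(n / 4), ncol = p) # pad with hom A2
  code[seq_len(n), ] <- ifelse(is.na(dos), 1L, c(3L, 2L, 0L)[dos + 1L])
  bytes <- code[seq(1, nrow(code), by = 4), , drop = FALSE] +
    4L * code[seq(2, nrow(code), by = 4), , drop = FALSE] +
    16L * code[seq(3, nrow(code), by = 4), , drop = FALSE] +
    64L * code[seq(4, nrow(code), by = 4), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb"); on.exit(close(con))
  writeBin(as.raw(c(108L, 27L, 1L)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' SNP and individual quality control
#'
#' Applies the four marker QC criteria sequentially: individuals with call
#' rate not exceeding `ind_call_min` are removed first; then SNPs are removed
#' when their call rate is not above `snp_call_min`, their minor allele
#' frequency (computed on the retained individuals) is not above `maf_min`,
#' or (with `autosomal_only`) they are not autosomal with a known position.
#' All retention rules are strict inequalities, matching PLINK.
#'
#' @param g A [genotype_matrix].
#' @param ind_call_min Individual call-rate threshold (keep if > 0.90).
#' @param snp_call_min SNP call-rate threshold (keep if > 0.95).
#' @param maf_min MAF threshold (keep if > 0.05).
#' @param autosomal_only Keep only autosomal SNPs with known positions.
#' @return A filtered [genotype_matrix]; row and column order preserved.
#' @export
snp_qc <- function(g, ind_call_min = 0.90, snp_call_min = 0.95,
                   maf_min = 0.05, autosomal_only = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  stopifnot(ind_call_min >= 0, ind_call_min <= 1, snp_call_min >= 0,
            snp_call_min <= 1, maf_min >= 0, maf_min <= 1)
  dos <- g$dosages
  ind_cr <- rowMeans(!is.na(dos))
  keep_ind <- ind_cr > ind_call_min
  if (!any(keep_ind)) {
    stop(sprintf("all %d individuals removed by call rate > %g", nrow(dos), ind_call_min),
         call. = FALSE)
  }
  dos2 <- dos[keep_ind, , drop = FALSE]
  snp_cr <- colMeans(!is.na(dos2))
  p_hat <- colMeans(dos2, na.rm = TRUE) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  maf[is.nan(maf)] <- 0
  keep_snp <- snp_cr > snp_call_min & maf > maf_min
  if (autosomal_only) keep_snp <- keep_snp & g$snp_meta$is_autosomal
  if (!any(keep_snp)) {
    stop(sprintf(
      "all %d SNPs removed (call rate <= %g: %d; MAF <= %g: %d; non-autosomal: %d)",
      ncol(dos), snp_call_min, sum(snp_cr <= snp_call_min),
      maf_min, sum(maf <= maf_min),
      if (autosomal_only) sum(!g$snp_meta$is_autosomal) else 0L), call. = FALSE)
  }
  genotype_matrix(dos2[, keep_snp, drop = FALSE],
                  snp_meta = g$snp_meta[keep_snp, , drop = FALSE])
}

#' Impute missing dosages by the per-SNP mean
#'
#' @param g A [genotype_matrix].
#' @return A `genotype_matrix` with missing dosages replaced by the SNP's mean
#'   dosage (real-valued, so downstream code treats dosages as numeric).
#' @export
impute_missing <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  dos <- g$dosages
  all_missing <- colSums(!is.na(dos)) == 0
  if (any(all_missing)) {
    stop("SNP(s) with no observed genotypes: ",
         paste(utils::head(colnames(dos)[all_missing], 5), collapse = ", "), call. = FALSE)
  }
  if (anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2]]
  }
  out <- g
  out$dosages <- dos
  out
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' Centers each SNP by twice its observed allele frequency and scales by
#' `2 * sum(p (1 - p))`: `G = W W' / (2 sum p(1-p))`. A small multiple of the
#' identity is blended in so that G is safely positive definite inside the
#' sampler: `blend_weight * I + (1 - blend_weight) * G`.
#'
#' @param g A [genotype_matrix] with no missing dosages (run [impute_missing()]
#'   first); at least 2 SNPs.
#' @param blend_weight Fraction of identity blended in (default 0.01).
#' @return A `grm` object: list with `values` (symmetric matrix with animal id
#'   dimnames), `blend_weight`, `n_snps`.
#' @export
compute_grm <- function(g, blend_weight = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"))
  stopifnot(blend_weight >= 0, blend_weight < 1)
  dos <- g$dosages
  if (anyNA(dos)) stop("missing dosages: impute first (impute_missing)", call. = FALSE)
  if (ncol(dos) < 2) stop("need at least 2 SNPs", call. = FALSE)
  p_hat <- colMeans(dos) / 2
  denom <- 2 * sum(p_hat * (1 - p_hat))
  if (denom <= 0) stop("all SNPs monomorphic: zero VanRaden denominator", call. = FALSE)
  W <- sweep(dos, 2, 2 * p_hat)
  G <- tcrossprod(W) / denom
  G <- blend_weight * diag(nrow(G)) + (1 - blend_weight) * G
  dimnames(G) <- list(rownames(dos), rownames(dos))
  structure(list(values = G, blend_weight = blend_weight, n_snps = ncol(dos)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d animals, %d SNPs, blend %.3g (mean diagonal %.3f)\n",
              nrow(x$values), x$n_snps, x$blend_weight, mean(diag(x$values))))
  invisible(x)
}

#' Write a GRM as a square TSV with an id header row
#' @param grm A `grm` object or matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grm <- function(grm, path) {
  G <- if (inherits(grm, "grm")) grm$values else as.matrix(grm)
  utils::write.table(G, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a GRM written by [write_grm()]
#' @param path Path to the square TSV.
#' @return A `grm` object (blend weight unknown, recorded as NA).
#' @export
read_grm <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  G <- as.matrix(df)
  colnames(G) <- rownames(G)
  structure(list(values = G, blend_weight = NA_real_, n_snps = NA_integer_),
            class = "grm")
}
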