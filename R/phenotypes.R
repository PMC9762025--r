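#' Average daily gain from weekly body weights
#'
#' ADG (g/day) is the slope of the within-animal ordinary least-squares
#' regression of body weight on age. One slope per animal.
#'
#' @param weights Data frame with columns `animal_id`, `age_days`, `weight_g`
#'   (long format, one row per weighing).
#' @return Tibble with columns `animal_id`, `adg` (g/day), `n_obs`.
#' @export
compute_adg <- function(weights) {
  weights <- tibble::as_tibble(weights)
  stopifnot(all(c("animal_id", "age_days", "weight_g") %in% names(weights)))
  if (any(weights$age_days <= 0) || any(weights$weight_g <= 0)) {
    stop("ages and weights must be positive", call. = FALSE)
  }
  weights |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(adg = ols_slope(.data$age_days, .data$weight_g),
                     n_obs = dplyr::n(), .groups = "drop")
}

ols_slope <- function(x, y) {
  if (length(x) < 2L) stop("ADG needs at least 2 body-weight records", call. = FALSE)
  if (length(unique(x)) < 2L) stop("ADG needs at least 2 distinct ages", call. = FALSE)
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

#' Validate a phenotype/covariate table
#'
#' Checks the per-animal record layout of the growth study: feeding regime
#' determines which ADG trait is observed (`adg_al` under ad libitum, `adg_r`
#' under restriction; exactly one per animal), batch-farm and weaning-weight
#' class are the systematic effects, litter and cage index the permanent
#' environmental effects. A litter contributing more than two animals to the
#' same cage (which would confound cage and maternal effects) triggers a
#' warning only.
#'
#' @param phenotypes Data frame with columns `animal_id`, `regime` ("AL"/"R"),
#'   `adg_al`, `adg_r`, `batch_farm`, `ww_class`, `litter_id`, `cage_id`.
#' @return The validated table as a tibble (invisibly usable in a pipe).
#' @export
validate_phenotypes <- function(phenotypes) {
  p <- tibble::as_tibble(phenotypes)
  need <- c("animal_id", "regime", "adg_al", "adg_r",
            "batch_farm", "ww_class", "litter_id", "cage_id")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("phenotype table misses columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(p$animal_id)) stop("duplicated animal ids", call. = FALSE)
  if (!all(p$regime %in% c("AL", "R"))) stop("regime must be 'AL' or 'R'", call. = FALSE)
  bad <- (p$regime == "AL" & (is.na(p$adg_al) | !is.na(p$adg_r))) |
         (p$regime == "R"  & (is.na(p$adg_r)  | !is.na(p$adg_al)))
  if (any(bad)) {
    stop("regime must determine the observed ADG slot (one observed, one missing); ",
         "offending animals: ", paste(utils::head(p$animal_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(p$litter_id) || anyNA(p$cage_id)) {
    stop("litter and cage ids must be non-missing", call. = FALSE)
  }
  overfull <- p |>
    dplyr::count(.data$litter_id, .data$cage_id) |>
    dplyr::filter(.data$n > 2)
  if (nrow(overfull)) {
    warning(sprintf("%d litter-cage combinations hold more than 2 animals", nrow(overfull)),
            call. = FALSE)
  }
  p
}

#' Assemble the per-OTU analysis dataset
#'
#' Joins one OTU's normalized abundance with the two ADG traits (one missing
#' per animal by design), the systematic effects and the litter/cage/animal
#' indices, aligned with the ordering of the genomic relationship matrix.
#'
#' @param phenotypes Phenotype table (see [validate_phenotypes()]), with
#'   `animal_id` matching the microbiome sample ids and GRM ids.
#' @param norm_table A `normalized_otu_table` from [css_normalize()].
#' @param otu_id The OTU to analyse (must be a column of `norm_table`).
#' @param grm A `grm` object from [compute_grm()] (or a symmetric matrix with
#'   dimnames), covering every phenotyped animal.
#' @return A `sem_dataset`: list with `records` tibble (in GRM order), the
#'   GRM matrix `G`, the OTU id and design sizes.
#' @export
assemble_sem_dataset <- function(phenotypes, norm_table, otu_id, grm) {
  p <- validate_phenotypes(phenotypes)
  stopifnot(inherits(norm_table, "normalized_otu_table"))
  if (!otu_id %in% colnames(norm_table$values)) {
    stop("OTU '", otu_id, "' not found in the normalized table", call. = FALSE)
  }
  G <- if (inherits(grm, "grm")) grm$values else as.matrix(grm)
  gids <- rownames(G)
  if (is.null(gids)) stop("GRM must carry animal ids as dimnames", call. = FALSE)

  no_micro <- setdiff(p$animal_id, rownames(norm_table$values))
  no_geno <- setdiff(p$animal_id, gids)
  if (length(no_micro) || length(no_geno)) {
    stop("unmatched animal ids - missing microbiome: [",
         paste(no_micro, collapse = ", "), "]; missing genotype: [",
         paste(no_geno, collapse = ", "), "]", call. = FALSE)
  }
  keep <- gids[gids %in% p$animal_id]
  G <- G[keep, keep, drop = FALSE]
  p <- p[match(keep, p$animal_id), , drop = FALSE]
  records <- p |>
    dplyr::mutate(
      y_m = unname(norm_table$values[match(.data$animal_id, rownames(norm_table$values)), otu_id]),
      batch_farm = factor(.data$batch_farm),
      ww_class = factor(.data$ww_class),
      litter = as.integer(factor(.data$litter_id)),
      cage = as.integer(factor(.data$cage_id)))
  sem_dataset(records, G, otu_id,
              scale = if (isTRUE(norm_table$log2_transform)) "log2-CSS" else "CSS")
}

#' Construct a `sem_dataset` directly from aligned components
#'
#' Lower-level constructor used by [assemble_sem_dataset()] and the synthetic
#' generator. `records` rows must already be aligned with the rows of `G`.
#'
#' @param records Tibble with columns `animal_id`, `adg_al`, `adg_r`, `y_m`,
#'   `batch_farm`, `ww_class`, `litter`, `cage` (litter/cage as integer codes).
#' @param G Genomic relationship matrix aligned with `records`, or `NULL` for
#'   unrelated animals (identity relationships).
#' @param otu_id Identifier carried through to results.
#' @param scale Measurement-scale label for the abundance values.
#' @return A `sem_dataset` object.
#' @export
sem_dataset <- function(records, G, otu_id = "OTU", scale = "CSS") {
  records <- tibble::as_tibble(records)
  need <- c("animal_id", "adg_al", "adg_r", "y_m", "batch_farm", "ww_class",
            "litter", "cage")
  stopifnot(all(need %in% names(records)))
  n <- nrow(records)
  if (!is.null(G)) {
    G <- as.matrix(G)
    stopifnot(nrow(G) == n, ncol(G) == n)
  }
  one_each <- xor(is.na(records$adg_al), is.na(records$adg_r))
  if (!all(one_each)) {
    stop("each animal must have exactly one of adg_al/adg_r observed", call. = FALSE)
  }
  if (anyNA(records$y_m)) stop("abundance y_m must be observed for all animals", call. = FALSE)
  records$batch_farm <- factor(records$batch_farm)
  records$ww_class <- factor(records$ww_class)
  structure(list(records = records, G = G, otu_id = otu_id, scale = scale,
                 sizes = c(n = n,
                           n_litters = length(unique(records$litter)),
                           n_cages = length(unique(records$cage)),
                           n_batches = nlevels(records$batch_farm))),
            class = "sem_dataset")
}

#' @export
print.sem_dataset <- function(x, ...) {
  s <- x$sizes
  cat(sprintf("<sem_dataset> OTU %s: %d animals, %d litters, %d cages, %d batch-farm levels (%s scale)\n",
              x$otu_id, s[["n"]], s[["n_litters"]], s[["n_cages"]], s[["n_batches"]], x$scale))
  invisible(x)
}
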