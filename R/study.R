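#' Run the per-OTU analysis loop
#'
#' Fits the recursive model once per OTU (each fit treats that OTU's
#' CSS-normalized abundance as the mediator trait), decomposes the posterior,
#' and collects one wide results row per OTU. Per-OTU seeds are derived
#' deterministically from the base seed, so the loop is reproducible and
#' resumable: with `out_file` set, completed rows are streamed to disk and a
#' re-run with `resume = TRUE` skips OTUs already present, producing the same
#' final table as an uninterrupted run. A sampler failure is logged and
#' recorded as an NA row; the loop continues.
#'
#' @param phenotypes Phenotype table (see [validate_phenotypes()]).
#' @param norm_table A `normalized_otu_table`.
#' @param grm A `grm` object covering all phenotyped animals.
#' @param otu_ids Subset of OTU ids to analyse (default: all columns of
#'   `norm_table`, in column order).
#' @param config A [sem_chain_config()]; its seed is the base seed.
#' @param trait_sd Optional named SDs `c(AL=, R=)` for standardization
#'   (default: observed phenotypic SDs).
#' @param hpd_prob,relevance_threshold Decision thresholds.
#' @param out_file Optional TSV path for streaming results.
#' @param resume Skip OTUs already present in `out_file`.
#' @param verbose Print one progress line per OTU.
#' @return A `study_results` tibble, one row per OTU, in `otu_ids` order.
#' @export
run_study <- function(phenotypes, norm_table, grm, otu_ids = NULL,
                      config = sem_chain_config(), trait_sd = NULL,
                      hpd_prob = 0.95, relevance_threshold = 0.2,
                      out_file = NULL, resume = FALSE, verbose = FALSE) {
  stopifnot(inherits(norm_table, "normalized_otu_table"))
  if (is.null(otu_ids)) otu_ids <- colnames(norm_table$values)
  done <- NULL
  if (resume && !is.null(out_file) && file.exists(out_file)) {
    done <- readr::read_tsv(out_file, show_col_types = FALSE)
    done <- done[done$otu_id %in% otu_ids, , drop = FALSE]
  }
  tax <- norm_table$taxonomy

  rows <- purrr::map(seq_along(otu_ids), function(i) {
    oid <- otu_ids[[i]]
    if (!is.null(done) && oid %in% done$otu_id) {
      return(done[done$otu_id == oid, , drop = FALSE][1, ])
    }
    seed_i <- otu_seed(config$seed, oid)
    cfg <- config
    cfg$seed <- as.integer(seed_i)
    row <- tryCatch({
      ds <- assemble_sem_dataset(phenotypes, norm_table, oid, grm)
      t0 <- Sys.time()
      fit <- fit_sem(ds, cfg)
      dec <- decompose_posterior(fit, trait_sd = trait_sd, hpd_prob = hpd_prob,
                                 relevance_threshold = relevance_threshold)
      rt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      if (verbose) {
        message(sprintf("OTU %s: seed %d, ESS(lambda) %.0f/%.0f, %.1fs",
                        oid, cfg$seed, fit$ess[["lambda_AL"]],
                        fit$ess[["lambda_R"]], rt))
      }
      result_row(oid, dec, fit, seed_i, rt)
    }, error = function(e) {
      warning(sprintf("OTU %s failed: %s", oid, conditionMessage(e)), call. = FALSE)
      na_result_row(oid, seed_i)
    })
    row$taxonomy <- if (!is.null(tax) && oid %in% tax$otu_id) {
      tax$taxonomy[match(oid, tax$otu_id)]
    } else NA_character_
    if (!is.null(out_file)) {
      written <- dplyr::bind_rows(if (is.null(done)) NULL else done, row)
      readr::write_tsv(written, out_file)
      done <<- written
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  out <- out[match(otu_ids, out$otu_id), , drop = FALSE]
  if (!is.null(out_file)) readr::write_tsv(out, out_file)
  class(out) <- c("study_results", class(out))
  out
}

# Deterministic per-OTU seed from the base seed and the OTU id, so a subset
# or resumed run reproduces the full run OTU by OTU.
otu_seed <- function(base_seed, otu_id) {
  h <- sum(utf8ToInt(otu_id) * seq_along(utf8ToInt(otu_id))) %% 65536L
  as.integer((base_seed + 7919L * h) %% .Machine$integer.max)
}

result_row <- function(otu_id, dec, fit, seed, runtime) {
  wide <- dec |>
    tidyr::pivot_wider(names_from = "trait",
                       values_from = !dplyr::all_of("trait"),
                       names_glue = "{.value}_{tolower(trait)}")
  alr <- attr(dec, "gcov_al_r")
  dplyr::bind_cols(
    tibble::tibble(otu_id = otu_id), wide,
    tibble::tibble(gcov_al_r_total = alr[["total"]],
                   gcov_al_r_direct = alr[["direct"]],
                   gcov_al_r_mediated = alr[["mediated"]],
                   h2_m = attr(dec, "h2_m"),
                   ess_lambda_al = fit$ess[["lambda_AL"]],
                   ess_lambda_r = fit$ess[["lambda_R"]],
                   seed = seed, runtime_s = runtime))
}

na_result_row <- function(otu_id, seed) {
  tmpl <- c(paste0(rep(c("lambda_mean", "lambda_median", "lambda_hpd_lower",
                         "lambda_hpd_upper", "std_effect", "gvar_total",
                         "gvar_direct", "gvar_indirect", "gcov_m_total",
                         "gcov_m_direct", "gcov_m_indirect", "h2_direct",
                         "h2_total"), 2),
                   rep(c("_al", "_r"), each = 13)),
            "gcov_al_r_total", "gcov_al_r_direct", "gcov_al_r_mediated",
            "h2_m", "ess_lambda_al", "ess_lambda_r", "runtime_s")
  row <- tibble::tibble(otu_id = otu_id)
  for (nm in tmpl) row[[nm]] <- NA_real_
  row$significant_al <- NA; row$significant_r <- NA
  row$relevant_al <- NA; row$relevant_r <- NA
  row$seed <- seed
  row
}

#' Extract the family rank from a taxonomy string
#'
#' Understands Greengenes rank-prefixed strings (`"...; f__Lachnospiraceae; ..."`)
#' and plain `"Family Lachnospiraceae"` labels. Strings without family-level
#' information (including `"Unassigned"` and empty `f__`) map to
#' `"Unassigned"`.
#'
#' @param taxonomy Character vector of taxonomy strings.
#' @return Character vector of family names.
#' @export
taxonomy_family <- function(taxonomy) {
  out <- rep("Unassigned", length(taxonomy))
  taxonomy <- as.character(taxonomy)
  gg <- stringr::str_match(taxonomy, "f__\\s*([^;]*)")[, 2]
  gg <- stringr::str_trim(gg)
  has_gg <- !is.na(gg) & gg != ""
  out[has_gg] <- gg[has_gg]
  plain <- stringr::str_match(taxonomy, "^Family\\s+(\\S.*)$")[, 2]
  has_plain <- !is.na(plain)
  out[has_plain] <- stringr::str_trim(plain[has_plain])
  out
}

#' Summarize a study's per-OTU results
#'
#' Counts of OTUs with significant structural coefficients per growth trait
#' and on both (the Venn counts satisfy inclusion-exclusion by construction),
#' positive/negative splits by the sign of the posterior mean, tables of the
#' relevant OTUs sorted by descending absolute standardized effect,
#' family-level percentage breakdowns, and heritability summaries across
#' OTUs.
#'
#' @param results A `study_results` tibble from [run_study()] (rows with NA
#'   flags are dropped with a message).
#' @return A `study_summary` list.
#' @export
summarize_study <- function(results) {
  r <- tibble::as_tibble(results)
  bad <- is.na(r$significant_al) | is.na(r$significant_r)
  if (any(bad)) {
    message(sum(bad), " OTU row(s) with missing flags dropped from the summary")
    r <- r[!bad, , drop = FALSE]
  }
  sig_al <- r$otu_id[r$significant_al]
  sig_r <- r$otu_id[r$significant_r]
  both <- intersect(sig_al, sig_r)
  counts <- list(
    n_sig_al = length(sig_al), n_sig_r = length(sig_r),
    n_sig_both = length(both),
    n_sig_total = length(union(sig_al, sig_r)),
    n_pos_al = sum(r$significant_al & r$lambda_mean_al > 0),
    n_neg_al = sum(r$significant_al & r$lambda_mean_al < 0),
    n_pos_r = sum(r$significant_r & r$lambda_mean_r > 0),
    n_neg_r = sum(r$significant_r & r$lambda_mean_r < 0))
  stopifnot(counts$n_sig_total == counts$n_sig_al + counts$n_sig_r - counts$n_sig_both)

  if (!"taxonomy" %in% names(r)) r$taxonomy <- NA_character_
  fam <- taxonomy_family(r$taxonomy)
  fam_breakdown <- function(ids) {
    f <- fam[r$otu_id %in% ids]
    if (!length(f)) return(tibble::tibble(family = character(), n = integer(),
                                          pct = numeric()))
    tibble::tibble(family = f) |>
      dplyr::count(.data$family, sort = TRUE) |>
      dplyr::mutate(pct = round(100 * .data$n / sum(.data$n)))
  }
  relevant_tbl <- function(trait) {
    flag <- r[[paste0("relevant_", trait)]]
    eff <- r[[paste0("std_effect_", trait)]]
    r[which(flag), , drop = FALSE] |>
      dplyr::arrange(dplyr::desc(abs(.data[[paste0("std_effect_", trait)]]))) |>
      dplyr::select("otu_id", "taxonomy",
                    dplyr::all_of(paste0(c("lambda_mean_", "lambda_median_",
                                           "lambda_hpd_lower_", "lambda_hpd_upper_",
                                           "std_effect_"), trait)))
  }
  h2 <- list(
    adg_al = c(mean = mean(r$h2_total_al), sd = stats::sd(r$h2_total_al)),
    adg_r = c(mean = mean(r$h2_total_r), sd = stats::sd(r$h2_total_r)),
    adg_al_direct = c(mean = mean(r$h2_direct_al), sd = stats::sd(r$h2_direct_al)),
    adg_r_direct = c(mean = mean(r$h2_direct_r), sd = stats::sd(r$h2_direct_r)),
    otu = c(mean = mean(r$h2_m), sd = stats::sd(r$h2_m)))
  structure(list(
    counts = counts,
    relevant_al = relevant_tbl("al"),
    relevant_r = relevant_tbl("r"),
    family_positive = list(al = fam_breakdown(r$otu_id[r$significant_al & r$lambda_mean_al > 0]),
                           r = fam_breakdown(r$otu_id[r$significant_r & r$lambda_mean_r > 0])),
    family_negative = list(al = fam_breakdown(r$otu_id[r$significant_al & r$lambda_mean_al < 0]),
                           r = fam_breakdown(r$otu_id[r$significant_r & r$lambda_mean_r < 0])),
    heritability = h2,
    n_otus = nrow(r)), class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  ct <- x$counts
  cat(sprintf("<study_summary> %d OTUs analysed\n", x$n_otus))
  cat(sprintf("  significant: %d on ADG_AL, %d on ADG_R, %d on both (%d total)\n",
              ct$n_sig_al, ct$n_sig_r, ct$n_sig_both, ct$n_sig_total))
  cat(sprintf("  relevant: %d on ADG_AL, %d on ADG_R\n",
              nrow(x$relevant_al), nrow(x$relevant_r)))
  invisible(x)
}

#' Summaries of a relevant-OTU table
#'
#' Venn counts and sign splits for a long-format table of relevant OTUs (one
#' row per OTU and growth trait), the layout of the published-style summary
#' tables: counts per trait, the ids affecting both traits, positive and
#' negative counts by the sign of the posterior mean, and integer-rounded
#' positive percentages.
#'
#' @param tbl Tibble with columns `otu_id`, `trait` ("AL"/"R"), `mean`,
#'   `effect`.
#' @return A list of counts, shared ids and percentages.
#' @export
summarize_relevant <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  stopifnot(all(c("otu_id", "trait", "mean", "effect") %in% names(tbl)))
  al <- tbl[tbl$trait == "AL", , drop = FALSE]
  r <- tbl[tbl$trait == "R", , drop = FALSE]
  shared <- intersect(al$otu_id, r$otu_id)
  shared_sign <- vapply(shared, function(id) {
    sign(al$mean[match(id, al$otu_id)]) * sign(r$mean[match(id, r$otu_id)])
  }, numeric(1))
  list(n_al = nrow(al), n_r = nrow(r), n_both = length(shared),
       shared_ids = shared,
       shared_all_negative = length(shared) > 0 &&
         all(al$mean[match(shared, al$otu_id)] < 0) &&
         all(r$mean[match(shared, r$otu_id)] < 0),
       n_pos_al = sum(al$mean > 0), n_neg_al = sum(al$mean < 0),
       n_pos_r = sum(r$mean > 0), n_neg_r = sum(r$mean < 0),
       pct_pos_al = round(100 * sum(al$mean > 0) / nrow(al)),
       pct_pos_r = round(100 * sum(r$mean > 0) / nrow(r)))
}

#' Published relevant-OTU tables bundled as a test fixture
#'
#' The printed per-OTU posterior summaries for the OTUs with a standardized
#' effect of at least 0.2 SD on either growth trait (15 for ADG_AL, 38 for
#' ADG_R). Three printed values are inconsistent in the source tables and are
#' stored corrected with a non-empty `flag` column: one effect with a sign
#' contradicting its negative posterior mean, and two garbled medians.
#'
#' @return Tibble with columns `otu_id`, `trait`, `mean`, `median`,
#'   `hpd_lower`, `hpd_upper`, `effect`, `taxonomy`, `flag`.
#' @export
load_fixture_tables <- function() {
  path <- system.file("extdata", "relevant_otu_tables.tsv", package = "microsem")
  stopifnot(nzchar(path))
  readr::read_tsv(path, show_col_types = FALSE, comment = "#") |>
    dplyr::mutate(flag = dplyr::coalesce(.data$flag, ""))
}

#' Bar chart of standardized effects for relevant OTUs
#' @param tbl Long-format relevant-OTU table (see [load_fixture_tables()]).
#' @return A ggplot object.
#' @export
plot_relevant_effects <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  ggplot2::ggplot(tbl, ggplot2::aes(x = stats::reorder(.data$otu_id, .data$effect),
                                    y = .data$effect, fill = .data$effect > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "effect (phenotypic SD per CSS unit)") +
    ggplot2::theme_minimal()
}
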