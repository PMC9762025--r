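#' Construct an OTU count table
#'
#' Container for raw 16S OTU counts, samples in rows and OTUs in columns,
#' with an optional taxonomy lookup. This is the entry point of the
#' preprocessing chain: [filter_otus()] then [css_normalize()].
#'
#' @param counts Non-negative integer matrix, samples x OTUs, with unique
#'   rownames (sample ids) and colnames (OTU ids).
#' @param taxonomy Optional data frame with columns `otu_id` and `taxonomy`
#'   (rank-prefixed Greengenes-style strings, e.g. `"k__Bacteria; p__..."`),
#'   keyed by a subset of the OTU ids.
#' @return An object of class `otu_counts`.
#' @export
otu_counts <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) stop("empty OTU count table", call. = FALSE)
  if (is.null(rownames(counts))) stop("counts must have sample ids as rownames", call. = FALSE)
  if (is.null(colnames(counts))) stop("counts must have OTU ids as colnames", call. = FALSE)
  if (anyDuplicated(rownames(counts))) stop("duplicated sample ids", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicated OTU ids", call. = FALSE)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  if (!is.null(taxonomy)) {
    taxonomy <- tibble::as_tibble(taxonomy)
    stopifnot(all(c("otu_id", "taxonomy") %in% names(taxonomy)))
    unknown <- setdiff(taxonomy$otu_id, colnames(counts))
    if (length(unknown)) {
      stop("taxonomy contains ids absent from the count table: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_counts")
}

#' @export
print.otu_counts <- function(x, ...) {
  cat(sprintf("<otu_counts> %d samples x %d OTUs, %s taxonomy\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$taxonomy)) "no" else "with"))
  invisible(x)
}

#' @export
dim.otu_counts <- function(x) dim(x$counts)

#' Read an OTU count table from TSV
#'
#' Reads a tab-separated count matrix. Orientation (whether rows are OTUs or
#' samples) is auto-detected by default: microbiome tables usually have far
#' more OTUs than samples, so the longer margin is taken as the OTU margin.
#'
#' @param path Path to a TSV file whose first column holds row identifiers.
#' @param orientation `"auto"`, `"samples_x_otus"`, or `"otus_x_samples"`.
#' @param taxonomy_path Optional 2-column TSV (otu_id, taxonomy) without header.
#' @return An [otu_counts] object (samples x OTUs internally).
#' @export
read_otu_counts <- function(path,
                            orientation = c("auto", "samples_x_otus", "otus_x_samples"),
                            taxonomy_path = NULL) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  tax <- NULL
  if (!is.null(taxonomy_path)) tax <- read_taxonomy(taxonomy_path)
  if (orientation == "auto") {
    # taxonomy ids identify the OTU margin unambiguously; otherwise take the
    # longer margin as the OTU margin (microbiome tables have many more OTUs
    # than samples)
    orientation <- if (!is.null(tax) && any(rownames(m) %in% tax$otu_id)) {
      "otus_x_samples"
    } else if (!is.null(tax) && any(colnames(m) %in% tax$otu_id)) {
      "samples_x_otus"
    } else if (nrow(m) >= ncol(m)) "otus_x_samples" else "samples_x_otus"
  }
  if (orientation == "otus_x_samples") m <- t(m)
  otu_counts(m, taxonomy = tax)
}

#' Read a 2-column taxonomy TSV (otu_id, taxonomy string)
#' @param path Path to a headerless 2-column TSV.
#' @return Tibble with columns `otu_id`, `taxonomy`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  tibble::tibble(otu_id = as.character(df[[1]]), taxonomy = as.character(df[[2]]))
}

#' Read an OTU table from a BIOM 2.x file
#'
#' Thin wrapper around the biomformat package. Taxonomy is pulled from the
#' observation metadata when present.
#'
#' @param path Path to a BIOM file.
#' @return An [otu_counts] object.
#' @export
read_biom_counts <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("reading BIOM files requires the 'biomformat' package", call. = FALSE)
  }
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix") # taxa x samples
  tax <- NULL
  om <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
  if (!is.null(om) && length(om)) {
    tax_chr <- vapply(seq_len(nrow(m)), function(i) {
      row <- om[i, , drop = TRUE]
      paste(unlist(row), collapse = "; ")
    }, character(1))
    tax <- tibble::tibble(otu_id = rownames(m), taxonomy = tax_chr)
  }
  otu_counts(t(m), taxonomy = tax)
}

#' Filter OTUs on prevalence and total relative abundance
#'
#' Discards rare features before modelling: an OTU is kept when it is detected
#' (count > 0) in at least `prevalence_min` of the samples AND its column sum
#' is at least `abundance_min` of the grand total of all counts. Values exactly
#' at a threshold are retained (the removal rule is strictly "less than").
#'
#' @param x An [otu_counts] object.
#' @param prevalence_min Minimum detection fraction across samples (default 0.05).
#' @param abundance_min Minimum share of the grand count total (default 1e-4,
#'   i.e. 0.01\%).
#' @return A filtered [otu_counts] object; sample set and column order unchanged.
#' @export
filter_otus <- function(x, prevalence_min = 0.05, abundance_min = 1e-4) {
  stopifnot(inherits(x, "otu_counts"))
  stopifnot(prevalence_min >= 0, prevalence_min <= 1,
            abundance_min >= 0, abundance_min <= 1)
  counts <- x$counts
  if (nrow(counts) == 0L || ncol(counts) == 0L) stop("empty OTU count table", call. = FALSE)
  prevalence <- colMeans(counts > 0)
  grand <- sum(counts)
  if (grand == 0) stop("count table is all zero", call. = FALSE)
  share <- colSums(counts) / grand
  keep <- prevalence >= prevalence_min & share >= abundance_min
  if (!any(keep)) {
    stop(sprintf(
      "all %d OTUs removed (%d failed prevalence >= %g, %d failed abundance >= %g)",
      ncol(counts), sum(prevalence < prevalence_min), prevalence_min,
      sum(share < abundance_min), abundance_min), call. = FALSE)
  }
  tax <- x$taxonomy
  if (!is.null(tax)) tax <- tax[tax$otu_id %in% colnames(counts)[keep], , drop = FALSE]
  otu_counts(counts[, keep, drop = FALSE], taxonomy = tax)
}

#' Cumulative sum scaling (CSS) normalization
#'
#' Library-size correction for OTU counts. For each sample j the scaling
#' factor s_j is the sum of that sample's counts that do not exceed the
#' `quantile`-level count of its positive-count distribution; normalized
#' values are `counts / s_j * reference_scale`. Unlike total-sum scaling,
#' the cumulative sum up to a quantile is robust to a few dominant taxa.
#'
#' @param x An [otu_counts] object (typically after [filter_otus()]).
#' @param quantile Quantile of each sample's positive counts defining the
#'   cumulative-sum cutoff; fixed default 0.5.
#' @param log2_transform If `TRUE`, return `log2(value + 1)`.
#' @param reference_scale `"median"` (median of the scaling factors, keeping
#'   values on a count-like scale) or a positive number for a fixed scale.
#' @return A `normalized_otu_table`: list with `values` (samples x OTUs),
#'   `scaling_factors`, `reference_scale`, `log2_transform`, `taxonomy`.
#' @export
css_normalize <- function(x, quantile = 0.5, log2_transform = FALSE,
                          reference_scale = "median") {
  stopifnot(inherits(x, "otu_counts"))
  stopifnot(is.numeric(quantile), quantile > 0, quantile < 1)
  counts <- x$counts
  s <- vapply(seq_len(nrow(counts)), function(i) {
    ci <- counts[i, ]
    pos <- ci[ci > 0]
    if (!length(pos)) return(0)
    cutoff <- stats::quantile(pos, probs = quantile, names = FALSE, type = 7)
    sum(ci[ci <= cutoff])
  }, numeric(1))
  if (any(s == 0)) {
    stop("zero CSS scaling factor for sample(s): ",
         paste(rownames(counts)[s == 0], collapse = ", "), call. = FALSE)
  }
  ref <- if (identical(reference_scale, "median")) stats::median(s) else {
    stopifnot(is.numeric(reference_scale), reference_scale > 0)
    as.numeric(reference_scale)
  }
  values <- counts / s * ref
  if (log2_transform) values <- log2(values + 1)
  structure(list(values = values,
                 scaling_factors = stats::setNames(s, rownames(counts)),
                 reference_scale = ref,
                 log2_transform = log2_transform,
                 taxonomy = x$taxonomy),
            class = "normalized_otu_table")
}

#' @export
print.normalized_otu_table <- function(x, ...) {
  cat(sprintf("<normalized_otu_table> %d samples x %d OTUs (CSS, ref %.3g%s)\n",
              nrow(x$values), ncol(x$values), x$reference_scale,
              if (x$log2_transform) ", log2" else ""))
  invisible(x)
}

#' Tidy an OTU table into long format
#'
#' @param x An `otu_counts` or `normalized_otu_table` object.
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `otu_id`, and `count` or `value`.
#' @export
tidy.otu_counts <- function(x, ...) {
  m <- x$counts
  tibble::tibble(sample_id = rep(rownames(m), times = ncol(m)),
                 otu_id = rep(colnames(m), each = nrow(m)),
                 count = as.vector(m))
}

#' @rdname tidy.otu_counts
#' @export
tidy.normalized_otu_table <- function(x, ...) {
  m <- x$values
  tibble::tibble(sample_id = rep(rownames(m), times = ncol(m)),
                 otu_id = rep(colnames(m), each = nrow(m)),
                 value = as.vector(m))
}
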