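#' Element-level activity matrix
#'
#' Holds elements x samples log2 RNA/DNA activity measures together with the
#' estimator that produced them and the per-element log2 aggregated DNA
#' abundance used for variance modeling.  Create with [summarize_dataset()].
#'
#' @name ElementActivityMatrix
#' @details Components: `element_ids`; `activity` (elements x samples, log2
#'   ratios); `estimator` (`"aggregate"` or `"average"`); `log2_dna`
#'   (elements x samples, log2 of 1 + library-size-corrected aggregated DNA);
#'   `mean_log2_dna` (across-sample row means of `log2_dna`);
#'   `common_lib_size` (the normalization target `L`).
NULL

#' @export
print.ElementActivityMatrix <- function(x, ...) {
  cat("ElementActivityMatrix:", length(x$element_ids), "elements x",
      ncol(x$activity), "samples (", x$estimator, "estimator )\n")
  invisible(x)
}

#' @export
dim.ElementActivityMatrix <- function(x) dim(x$activity)

# Aggregated, per-sample scaled counts and their log2(1 + .) transform.
.aggregate_tables <- function(counts) {
  counts <- .require_norm(counts)
  ord <- unique(counts$element)
  ragg <- rowsum(counts$rna, group = counts$element, reorder = FALSE)
  dagg <- rowsum(counts$dna, group = counts$element, reorder = FALSE)
  list(element_ids = ord,
       ragg = ragg[ord, , drop = FALSE],
       dagg = dagg[ord, , drop = FALSE],
       rna_sf = counts$rna_sf, dna_sf = counts$dna_sf)
}

#' Aggregate activity estimator
#'
#' Sums counts over an element's barcodes, then forms the offset log2 ratio
#' of library-size-corrected totals:
#' `log2((1 + (L/N_r) * sum(R_b)) / (1 + (L/N_d) * sum(D_b)))`.
#'
#' @param counts a normalized [BarcodeCountSet].
#' @param element element id.
#' @param sample sample id or index.
#' @return The log2 activity estimate (finite for all non-negative counts).
#' @export
aggregate_estimator <- function(counts, element, sample) {
  counts <- .require_norm(counts)
  sel <- counts$element == element
  if (!any(sel)) stop("lookup error: unknown element '", element, "'")
  s <- .resolve_sample(counts, sample)
  rs <- sum(counts$rna[sel, s])
  ds <- sum(counts$dna[sel, s])
  log2((1 + counts$rna_sf[s] * rs) / (1 + counts$dna_sf[s] * ds))
}

#' Average activity estimator
#'
#' Mean over an element's barcodes of per-barcode offset log2 ratios:
#' `(1/B) * sum(log2((R_b * L/N_r + 1) / (D_b * L/N_d + 1)))`.
#'
#' @inheritParams aggregate_estimator
#' @return The log2 activity estimate.
#' @export
average_estimator <- function(counts, element, sample) {
  counts <- .require_norm(counts)
  sel <- counts$element == element
  if (!any(sel)) stop("lookup error: unknown element '", element, "'")
  s <- .resolve_sample(counts, sample)
  mean(log2((counts$rna[sel, s] * counts$rna_sf[s] + 1) /
            (counts$dna[sel, s] * counts$dna_sf[s] + 1)))
}

.resolve_sample <- function(counts, sample) {
  if (is.character(sample)) {
    s <- match(sample, colnames(counts$rna))
    if (is.na(s)) stop("lookup error: unknown sample '", sample, "'")
    s
  } else {
    stopifnot(sample >= 1, sample <= ncol(counts$rna))
    as.integer(sample)
  }
}

#' Summarize barcode-level counts into element-level activities
#'
#' Applies the chosen estimator to every (element, sample) pair and computes
#' each element's mean log2 DNA abundance, the across-sample average of
#' `log2(1 + (L/N_d) * sum(D_b))`, which drives the precision-weight model.
#' For single-barcode elements the two estimators coincide exactly.
#'
#' @param counts a [BarcodeCountSet]; normalized with
#'   [total_count_normalize()] first (done implicitly with defaults if not).
#' @param estimator `"aggregate"` (default) or `"average"`.
#' @return An [ElementActivityMatrix].
#' @export
summarize_dataset <- function(counts, estimator = c("aggregate", "average")) {
  estimator <- match.arg(estimator)
  counts <- .require_norm(counts)
  agg <- .aggregate_tables(counts)
  rsc <- sweep(agg$ragg, 2L, agg$rna_sf, `*`)
  dsc <- sweep(agg$dagg, 2L, agg$dna_sf, `*`)
  if (estimator == "aggregate") {
    act <- log2(1 + rsc) - log2(1 + dsc)
  } else {
    lr <- log2(sweep(counts$rna, 2L, counts$rna_sf, `*`) + 1) -
          log2(sweep(counts$dna, 2L, counts$dna_sf, `*`) + 1)
    act <- rowsum(lr, group = counts$element, reorder = FALSE)
    act <- act[agg$element_ids, , drop = FALSE]
    B <- barcodes_per_element(counts)[agg$element_ids]
    act <- act / B
  }
  log2_dna <- log2(1 + dsc)
  structure(list(element_ids = agg$element_ids,
                 activity = act,
                 estimator = estimator,
                 log2_dna = log2_dna,
                 mean_log2_dna = rowMeans(log2_dna),
                 common_lib_size = counts$common_lib_size),
            class = "ElementActivityMatrix")
}
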