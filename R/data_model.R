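#' Barcode-level MPRA count container
#'
#' Bundles the barcode x sample RNA and DNA count matrices of an MPRA
#' experiment together with the barcode-to-element map, the sample sheet and
#' per-sample library sizes.  Barcodes are technical replicates of a
#' regulatory element; every barcode maps to exactly one element and the two
#' count matrices share barcode order and sample order.
#'
#' @param rna,dna non-negative integer matrices (barcodes x samples) with
#'   barcode ids as row names and sample ids as column names.
#' @param element character vector, one element id per barcode (parallel to
#'   the rows of `rna`).
#' @param samples sample sheet: a `data.frame` with columns `sample_id`,
#'   `condition` and optionally `block` (pair/replicate identifier for
#'   paired allelic designs) plus any extra covariates.  Defaults to a
#'   single-condition sheet built from the column names.
#' @param rna_lib_sizes,dna_lib_sizes positive per-sample library sizes;
#'   default to the column sums of the respective matrix.
#'
#' @return An object of class `BarcodeCountSet`: a list with components
#'   `rna`, `dna`, `element`, `samples`, `rna_lib_sizes`, `dna_lib_sizes`
#'   and, after [total_count_normalize()], `rna_sf`, `dna_sf`,
#'   `common_lib_size`.
#' @seealso [read_counts()], [total_count_normalize()], [summarize_dataset()]
#' @export
BarcodeCountSet <- function(rna, dna, element, samples = NULL,
                            rna_lib_sizes = NULL, dna_lib_sizes = NULL) {
  rna <- as.matrix(rna)
  dna <- as.matrix(dna)
  if (!identical(dim(rna), dim(dna)))
    stop("format error: 'rna' and 'dna' must have identical dimensions")
  if (!is.null(rownames(rna)) && !is.null(rownames(dna)) &&
      !identical(rownames(rna), rownames(dna)))
    stop("format error: 'rna' and 'dna' must share barcode order")
  if (!is.null(colnames(rna)) && !is.null(colnames(dna)) &&
      !identical(colnames(rna), colnames(dna)))
    stop("format error: 'rna' and 'dna' must share sample columns")
  .check_counts(rna, "rna")
  .check_counts(dna, "dna")
  if (length(element) != nrow(rna))
    stop("mapping error: 'element' must have one entry per barcode")
  element <- as.character(element)
  if (anyNA(element))
    stop("mapping error: barcode without element mapping")
  if (is.null(rownames(rna))) {
    rownames(rna) <- rownames(dna) <- paste0("bc", seq_len(nrow(rna)))
  }
  if (is.null(colnames(rna))) {
    colnames(rna) <- colnames(dna) <- paste0("s", seq_len(ncol(rna)))
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(rna),
                          condition = factor(rep("all", ncol(rna))),
                          stringsAsFactors = FALSE)
  }
  samples <- .check_samples(samples, colnames(rna))
  if (is.null(rna_lib_sizes)) rna_lib_sizes <- colSums(rna)
  if (is.null(dna_lib_sizes)) dna_lib_sizes <- colSums(dna)
  if (any(rna_lib_sizes <= 0) || any(dna_lib_sizes <= 0))
    stop("degenerate input: library sizes must be positive")
  rna_lib_sizes <- stats::setNames(as.numeric(rna_lib_sizes), colnames(rna))
  dna_lib_sizes <- stats::setNames(as.numeric(dna_lib_sizes), colnames(dna))
  structure(list(rna = rna, dna = dna, element = element,
                 samples = samples,
                 rna_lib_sizes = rna_lib_sizes,
                 dna_lib_sizes = dna_lib_sizes,
                 rna_sf = NULL, dna_sf = NULL, common_lib_size = NULL),
            class = "BarcodeCountSet")
}

.check_counts <- function(m, what) {
  if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m != round(m)))
    stop("parse error: '", what, "' counts must be non-negative integers")
  invisible(TRUE)
}

.check_samples <- function(samples, sample_ids) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(samples)))
    stop("format error: sample sheet needs 'sample_id' and 'condition' columns")
  if (!setequal(samples$sample_id, sample_ids))
    stop("format error: sample sheet ids do not match count matrix columns")
  samples <- samples[match(sample_ids, samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  samples$condition <- factor(samples$condition)
  if (nlevels(samples$condition) < 1)
    stop("format error: 'condition' must have at least one level")
  if ("block" %in% names(samples) && !all(is.na(samples$block))) {
    samples$block <- factor(samples$block)
    if (any(table(samples$block) < 2))
      stop("format error: every block must contain at least 2 samples")
  }
  samples
}

#' @export
print.BarcodeCountSet <- function(x, ...) {
  cat("BarcodeCountSet:", nrow(x$rna), "barcodes,",
      length(unique(x$element)), "elements,", ncol(x$rna), "samples\n")
  cat("  conditions:", paste(levels(x$samples$condition), collapse = ", "), "\n")
  if (!is.null(x$samples$block))
    cat("  blocks:", nlevels(factor(x$samples$block)), "\n")
  if (!is.null(x$common_lib_size))
    cat("  normalized to common library size",
        format(x$common_lib_size, digits = 6), "\n")
  invisible(x)
}

#' @export
dim.BarcodeCountSet <- function(x) dim(x$rna)

#' Number of barcodes per element
#'
#' @param counts a [BarcodeCountSet].
#' @return Named integer vector of barcode counts per element, in first
#'   appearance order.
#' @export
barcodes_per_element <- function(counts) {
  tab <- table(factor(counts$element, levels = unique(counts$element)))
  structure(as.integer(tab), names = names(tab))
}

#' Read barcode-level MPRA counts from delimited text files
#'
#' Canonical dialect: tab-separated, one header row of sample ids, first
#' column the barcode id.  The element map has two columns (barcode,
#' element); the sample sheet has columns `sample_id`, `condition` and
#' optionally `block`.
#'
#' @param rna_path,dna_path paths to the RNA and DNA count tables.
#' @param map_path path to the barcode-to-element map.
#' @param sample_path path to the sample sheet.
#' @return A validated [BarcodeCountSet]; library sizes are the column sums.
#' @export
read_counts <- function(rna_path, dna_path, map_path, sample_path) {
  for (p in c(rna_path, dna_path, map_path, sample_path))
    if (!file.exists(p)) stop("file not found: ", p)
  rna <- .read_count_table(rna_path)
  dna <- .read_count_table(dna_path)
  if (!identical(colnames(rna), colnames(dna)))
    stop("format error: sample columns of rna and dna tables disagree")
  map <- utils::read.delim(map_path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (ncol(map) < 2)
    stop("format error: element map needs two columns (barcode, element)")
  idx <- match(rownames(rna), map[[1]])
  if (anyNA(idx))
    stop("mapping error: barcode without element mapping: ",
         paste(utils::head(rownames(rna)[is.na(idx)], 3), collapse = ", "))
  if (!identical(sort(rownames(rna)), sort(rownames(dna))))
    stop("format error: rna and dna barcode ids disagree")
  dna <- dna[rownames(rna), , drop = FALSE]
  samples <- utils::read.delim(sample_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  BarcodeCountSet(rna, dna, element = map[[2]][idx], samples = samples)
}

.read_count_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = 1)
  m <- as.matrix(tab)
  if (!is.numeric(m))
    stop("parse error: non-numeric count field in ", path)
  .check_counts(m, basename(path))
  storage.mode(m) <- "integer"
  m
}

#' Write a BarcodeCountSet to delimited text files
#'
#' Inverse of [read_counts()] in the canonical tab-separated dialect;
#' `read_counts()` on the written files reproduces the object.
#'
#' @param counts a [BarcodeCountSet].
#' @param rna_path,dna_path,map_path,sample_path output file paths.
#' @return Invisibly, the four paths.
#' @export
write_counts <- function(counts, rna_path, dna_path, map_path, sample_path) {
  .write_count_table(counts$rna, rna_path)
  .write_count_table(counts$dna, dna_path)
  map <- data.frame(barcode = rownames(counts$rna),
                    element = counts$element)
  utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(counts$samples, sample_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(rna_path, dna_path, map_path, sample_path))
}

.write_count_table <- function(m, path) {
  df <- data.frame(barcode = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Total count normalization
#'
#' Records per-sample scale factors `L / N` that bring every RNA and DNA
#' library to a common library size `L`.  The raw integer counts are kept;
#' scaling is applied lazily inside the activity estimators, where the `+1`
#' offset is added after scaling.
#'
#' @param counts a [BarcodeCountSet].
#' @param common_lib_size the common library size `L`, or `"mean"` (default)
#'   for the grand mean of all RNA and DNA library sizes.
#' @return The input with `rna_sf`, `dna_sf` and `common_lib_size` filled in.
#' @export
total_count_normalize <- function(counts, common_lib_size = "mean") {
  stopifnot(inherits(counts, "BarcodeCountSet"))
  if (any(counts$rna_lib_sizes <= 0) || any(counts$dna_lib_sizes <= 0))
    stop("degenerate input: zero library size")
  L <- if (identical(common_lib_size, "mean")) {
    mean(c(counts$rna_lib_sizes, counts$dna_lib_sizes))
  } else {
    stopifnot(is.numeric(common_lib_size), common_lib_size > 0)
    as.numeric(common_lib_size)
  }
  counts$common_lib_size <- L
  counts$rna_sf <- unname(L / counts$rna_lib_sizes)
  counts$dna_sf <- unname(L / counts$dna_lib_sizes)
  counts
}

.require_norm <- function(counts) {
  if (is.null(counts$rna_sf)) counts <- total_count_normalize(counts)
  counts
}

#' Filter elements with unstable activity measures
#'
#' Drops elements whose aggregated (summed over barcodes) raw DNA count falls
#' below `min_dna` in any sample, and elements whose log-ratio activity is
#' identical across all samples (in practice, elements with all-zero RNA).
#' Both classes are clear outliers in the copy-number--variance relationship.
#'
#' @param activity an [ElementActivityMatrix].
#' @param counts the [BarcodeCountSet] the activities were computed from.
#' @param min_dna minimum aggregated DNA count required in every sample
#'   (default 10).
#' @return The filtered `ElementActivityMatrix`.  A `data.frame` of dropped
#'   elements and reasons is attached as attribute `"filter_report"`.
#' @export
filter_elements <- function(activity, counts, min_dna = 10) {
  stopifnot(inherits(activity, "ElementActivityMatrix"),
            inherits(counts, "BarcodeCountSet"))
  dagg <- rowsum(counts$dna, group = counts$element, reorder = FALSE)
  dagg <- dagg[activity$element_ids, , drop = FALSE]
  low_dna <- apply(dagg < min_dna, 1L, any)
  const <- apply(activity$activity, 1L, function(y) all(y == y[1L]))
  drop <- low_dna | const
  report <- data.frame(
    element_id = activity$element_ids[drop],
    reason = ifelse(low_dna[drop], "low_dna", "constant_log_ratio"),
    stringsAsFactors = FALSE)
  out <- .subset_eam(activity, !drop)
  if (length(out$element_ids) == 0L)
    warning("all elements removed by filtering")
  attr(out, "filter_report") <- report
  out
}

.subset_eam <- function(activity, keep) {
  activity$element_ids <- activity$element_ids[keep]
  activity$activity <- activity$activity[keep, , drop = FALSE]
  activity$mean_log2_dna <- activity$mean_log2_dna[keep]
  activity$log2_dna <- activity$log2_dna[keep, , drop = FALSE]
  activity
}
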