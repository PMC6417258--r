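#' Write a small deterministic example dataset to disk
#'
#' Generates a compact synthetic MPRA dataset with [generate_mpra()] and
#' writes it in the canonical tab-separated dialect, together with the
#' truth table.  Useful for examples, tests and pipeline smoke runs.
#'
#' @param kind `"tiny"` (20 elements, 3 barcodes, 3 vs 3), `"null"`
#'   (200 elements, fully null), `"signal"` (200 elements, 10% with a true
#'   log2 effect of 1) or `"paired"` (100 elements, 4 blocks of 2).
#' @param dir output directory (created if needed).
#' @param seed integer seed; the same seed regenerates identical files.
#' @return Invisibly, a named vector of the file paths written
#'   (`rna`, `dna`, `map`, `samples`, `truth`).
#' @export
make_fixture <- function(kind = c("tiny", "null", "signal", "paired"),
                         dir = tempfile("mpra_fixture_"), seed = 1) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    tiny = simulation_spec(n_elements = 20, barcodes_per_element = 3,
                           samples_per_group = c(3, 3), dna_lib_size = 2e4,
                           rna_lib_size = 2e4, seed = seed),
    null = simulation_spec(n_elements = 200, seed = seed),
    signal = simulation_spec(n_elements = 200, effect_fraction = 0.1,
                             effect_size = 1, seed = seed),
    paired = simulation_spec(n_elements = 100, samples_per_group = c(4, 4),
                             paired = TRUE, activity_noise_sd = 0.3,
                             within_block_correlation = 0.5, seed = seed))
  sim <- generate_mpra(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2L) != 0L) stop("I/O error: cannot write to ", dir)
  paths <- c(rna = file.path(dir, "rna.tsv"), dna = file.path(dir, "dna.tsv"),
             map = file.path(dir, "map.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_counts(sim$counts, paths["rna"], paths["dna"], paths["map"],
               paths["samples"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

.pipeline_keys <- c("rna", "dna", "map", "samples", "design", "estimator",
                    "span", "min_dna", "block", "coef", "out", "seed")

#' Run the full differential-activity pipeline from a configuration
#'
#' Reads counts from disk, fits [mpralm()] and writes a per-element result
#' table (element, logFC, t, df, p, BH-adjusted p) as a TSV with
#' `#`-prefixed metadata header lines recording the package version and the
#' resolved configuration.
#'
#' @param config a named list, or the path of a YAML file, with keys:
#'   `rna`, `dna`, `map`, `samples` (input paths; required), `design`
#'   (formula as a string, default `"~ condition"`), `estimator`, `span`,
#'   `min_dna`, `block`, `coef` (coefficient to report), `out` (output TSV
#'   path; required), `seed`.
#' @return Invisibly, the result `data.frame`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("config error: the 'yaml' package is needed to read YAML configs")
    if (!file.exists(config)) stop("config error: missing file: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  bad <- setdiff(names(config), .pipeline_keys)
  if (length(bad))
    stop("config error: unknown key(s): ", paste(bad, collapse = ", "))
  for (k in c("rna", "dna", "map", "samples", "out"))
    if (is.null(config[[k]])) stop("config error: missing required key '", k, "'")
  for (k in c("rna", "dna", "map", "samples"))
    if (!file.exists(config[[k]]))
      stop("config error: missing file: ", config[[k]])
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  counts <- read_counts(config$rna, config$dna, config$map, config$samples)
  design <- stats::as.formula(
    if (is.null(config$design)) "~ condition" else config$design)
  fit <- mpralm(counts, design,
                estimator = if (is.null(config$estimator)) "aggregate"
                            else config$estimator,
                span = if (is.null(config$span)) 0.3 else config$span,
                block = config$block,
                min_dna = if (is.null(config$min_dna)) 10 else config$min_dna)
  res <- top_elements(fit, coef = config$coef, sort_by = "none")
  hdr <- c(paste0("# mpratools version ",
                  as.character(utils::packageVersion("mpratools"))),
           paste0("# config: ",
                  paste(names(config), unlist(lapply(config, format)),
                        sep = "=", collapse = " ")))
  con <- file(config$out, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(res, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res)
}
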