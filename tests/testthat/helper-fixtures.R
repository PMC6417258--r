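# small hand-built barcode count set: 2 elements x 2 barcodes x 3 samples
tiny_counts <- function() {
  rna <- matrix(c(10, 12, 8,
                  5, 6, 7,
                  20, 18, 25,
                  2, 1, 3), nrow = 4, byrow = TRUE,
                dimnames = list(paste0("bc", 1:4), paste0("s", 1:3)))
  dna <- matrix(c(8, 9, 10,
                  6, 5, 6,
                  15, 16, 14,
                  4, 5, 4), nrow = 4, byrow = TRUE,
                dimnames = list(paste0("bc", 1:4), paste0("s", 1:3)))
  BarcodeCountSet(rna, dna, element = c("e1", "e1", "e2", "e2"),
                  samples = data.frame(sample_id = paste0("s", 1:3),
                                       condition = c("a", "a", "b")))
}

# counts with all library sizes forced equal, so scale factors are 1
unit_sf_counts <- function(rna, dna, element, samples = NULL, L = 100) {
  x <- BarcodeCountSet(rna, dna, element, samples = samples,
                       rna_lib_sizes = rep(L, ncol(rna)),
                       dna_lib_sizes = rep(L, ncol(rna)))
  total_count_normalize(x, common_lib_size = L)
}

# element-activity container built directly from matrices, for weight tests
manual_eam <- function(activity, log2_dna) {
  n <- nrow(activity)
  structure(list(element_ids = paste0("e", seq_len(n)),
                 activity = activity, estimator = "aggregate",
                 log2_dna = log2_dna,
                 mean_log2_dna = rowMeans(log2_dna),
                 common_lib_size = 1e6),
            class = "ElementActivityMatrix")
}

two_group_design <- function(n1, n2) {
  cbind(intercept = 1, group = rep(c(0, 1), c(n1, n2)))
}
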