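# Shared fixture builders. Everything is generated in code; tests that
# need files write them to tempfiles.

# small random RFU matrix (log-normal intensities)
toy_matrix <- function(n_samples, n_analytes, seed = 1L,
                       meanlog2 = 10, sdlog2 = 1) {
  set.seed(seed)
  m <- 2 ^ matrix(rnorm(n_samples * n_analytes, meanlog2, sdlog2),
                  nrow = n_samples,
                  dimnames = list(sprintf("S%03d", seq_len(n_samples)),
                                  sprintf("A%03d", seq_len(n_analytes))))
  m
}

# minimal clinical annotation for a matrix whose first n_cases rows are
# cases and the rest controls
toy_annotation <- function(m, n_cases, site = "SYNTH-KAR",
                           stage = "III") {
  n <- nrow(m)
  is_case <- seq_len(n) <= n_cases
  data.frame(
    sample_id = rownames(m),
    class_label = ifelse(is_case, "CASE", "CONTROL"),
    site = site,
    draw_type = ifelse(is_case, "INTRA_OP", "CLINIC"),
    subject_id = rownames(m),
    plate_id = "P01",
    stage = ifelse(is_case, stage, NA_character_),
    histology = ifelse(is_case, "EPITHELIAL", NA_character_),
    assay_version = "V1",
    stringsAsFactors = FALSE)
}

# a cleanly separable two-class matrix: panel analytes shifted in cases
separable_matrix <- function(n_cases = 20, n_controls = 20,
                             n_analytes = 13, shift = 4, seed = 1L) {
  set.seed(seed)
  n <- n_cases + n_controls
  base <- matrix(rnorm(n * n_analytes, 10, 0.3), nrow = n)
  base[seq_len(n_cases), ] <- base[seq_len(n_cases), ] + shift
  m <- 2 ^ base
  dimnames(m) <- list(sprintf("S%03d", seq_len(n)),
                      sprintf("A%03d", seq_len(n_analytes)))
  m
}

# reduced-size cohort spec for fast module tests
small_spec <- function(..., n_artifact_analytes = 10, seed = 1L) {
  cohort_spec(n_cases = 30, n_controls = 30, n_analytes = 200,
              n_true_markers = 5, n_weak_markers = 10,
              n_artifact_analytes = n_artifact_analytes, seed = seed, ...)
}
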