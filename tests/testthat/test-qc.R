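# brute-force two-sample KS oracle: evaluate both ECDFs at every pooled
# data point and take the largest absolute gap
ks_brute <- function(x, y) {
  pts <- c(x, y)
  max(sapply(pts, function(t) abs(mean(x <= t) - mean(y <= t))))
}

test_that("ks_distance matches exhaustive ECDF evaluation and stats::ks.test", {
  expect_equal(ks_distance(1:5, 1:5), 0)
  expect_equal(ks_distance(1:4, 11:14), 1)
  expect_equal(ks_distance(c(1, 2, 3, 4), c(3, 4, 5, 6)),
               ks_brute(c(1, 2, 3, 4), c(3, 4, 5, 6)))

  set.seed(31)
  for (i in 1:50) {
    n <- sample(2:50, 1); m <- sample(2:50, 1)
    x <- if (i %% 2) rnorm(n) else sample(1:8, n, replace = TRUE)
    y <- if (i %% 2) rnorm(m, 0.5) else sample(2:9, m, replace = TRUE)
    d <- ks_distance(x, y)
    expect_equal(d, ks_brute(x, y))
    expect_gte(d, 0); expect_lte(d, 1)
    # symmetric, and invariant under a joint strictly monotone transform
    expect_equal(d, ks_distance(y, x))
    expect_equal(d, ks_distance(exp(x / 3), exp(y / 3)))
    if (i %% 2 == 1)  # ks.test statistic agrees when there are no ties
      expect_equal(d, unname(suppressWarnings(ks.test(x, y)$statistic)))
  }
  expect_error(ks_distance(numeric(0), 1:3), "non-empty")
})

test_that("control-set KS filter excludes site-shifted analytes, not nulls", {
  # null: two identical-distribution control sites, exclusions near zero
  excl_null <- sapply(1:10, function(s) {
    set.seed(s)
    m <- toy_matrix(60, 300, seed = s)
    ann <- toy_annotation(m, n_cases = 0)
    ann$site <- rep(c("SYNTH-A", "SYNTH-B"), each = 30)
    mean(filter_ks_control_sets(m, ann)$excluded)
  })
  expect_lt(mean(excl_null), 0.02)

  # power: a +2 log2 shift between control sites is always excluded
  set.seed(77)
  m <- toy_matrix(60, 50, seed = 77)
  ann <- toy_annotation(m, n_cases = 0)
  ann$site <- rep(c("SYNTH-A", "SYNTH-B"), each = 30)
  m[31:60, 1:5] <- m[31:60, 1:5] * 64  # +6 log2 against noise SD 1
  frag <- filter_ks_control_sets(m, ann)
  expect_true(all(frag$excluded[1:5]))
  expect_true(all(frag$max_ks[1:5] > 0.9))

  # threshold 1 can never exclude (D <= 1, strict inequality)
  expect_false(any(filter_ks_control_sets(m, ann, threshold = 1)$excluded))

  # fewer than two eligible sites is an error
  ann$site <- "SYNTH-A"
  expect_error(filter_ks_control_sets(m, ann), ">= 2 control sites")
})

test_that("paired-draw filter controls type-I error and detects shifts", {
  # type-I: 12 null subjects x 1000 analytes, conjunction rule
  set.seed(5)
  lv <- matrix(rnorm(24 * 1000, 10, 0.5), nrow = 24)
  dimnames(lv) <- list(c(paste0("PS", 1:12, "_PRE"),
                         paste0("PS", 1:12, "_INTRA")),
                       sprintf("A%04d", 1:1000))
  ann <- data.frame(sample_id = rownames(lv), class_label = "CONTROL",
                    site = "SYNTH-KAR",
                    draw_type = rep(c("PRE_OP", "INTRA_OP"), each = 12),
                    subject_id = rep(paste0("PS", 1:12), 2),
                    plate_id = "P01", stage = NA, histology = NA,
                    assay_version = "V1")
  frag <- filter_paired_draws(2^lv, ann)
  expect_lte(mean(frag$excluded), 0.05)

  # power: spec'd 1.5 log2 artifact shifts are excluded >= 95% of the time
  rates <- sapply(1:20, function(s) {
    spec <- small_spec(seed = s)
    pd <- generate_paired_draws(spec)
    art <- generate_cohort(spec)$truth$artifact_analyte_ids
    fr <- filter_paired_draws(pd$matrix, pd$annotation)
    mean(fr$excluded[fr$analyte_id %in% art])
  })
  expect_gte(mean(rates), 0.95)

  # literally identical paired values: p = 1, shift 0, never excluded
  m1 <- matrix(rep(c(100, 200, 300, 400), 2), ncol = 1,
               dimnames = list(paste0("S", 1:8), "A001"))
  ann1 <- data.frame(sample_id = rownames(m1), class_label = "CONTROL",
                     site = "SYNTH-KAR",
                     draw_type = rep(c("PRE_OP", "INTRA_OP"), each = 4),
                     subject_id = rep(paste0("PS", 1:4), 2),
                     plate_id = "P01", stage = NA, histology = NA,
                     assay_version = "V1")
  fr1 <- filter_paired_draws(m1, ann1)
  expect_equal(fr1$p_value, 1)
  expect_equal(fr1$median_log2_ratio, 0)
  expect_false(fr1$excluded)
})

test_that("PCA screen flags a degraded control sub-cohort and spares nulls", {
  # study geometry: a 30-sample degraded control set inside a ~190-sample
  # cohort measured on the full analyte panel
  hits <- sapply(1:6, function(s) {
    spec <- cohort_spec(n_cases = 79, n_controls = 110,
                        control_sites = c("SYNTH-KAR", "SYNTH-LIB",
                                          "SYNTH-SIN"),
                        controls_per_site = c("SYNTH-KAR" = 40,
                                              "SYNTH-LIB" = 40,
                                              "SYNTH-SIN" = 30),
                        degraded_fraction = 1, seed = s)
    co <- generate_cohort(spec)
    sc <- pca_artifact_screen(co$matrix, co$annotation)
    degr <- co$truth$degraded_sample_ids
    length(sc$flagged_components) > 0 &&
      mean(degr %in% sc$flagged_samples$sample_id) >= 0.9
  })
  expect_gte(sum(hits), 5)

  # covariate-free null: no flagged components
  null_flags <- sapply(1:10, function(s) {
    m <- toy_matrix(40, 300, seed = 100 + s)
    ann <- toy_annotation(m, n_cases = 0)
    ann$site <- rep(c("SYNTH-A", "SYNTH-B"), 20)
    ann$plate_id <- rep(c("P01", "P02"), each = 20)
    length(pca_artifact_screen(m, ann)$flagged_components)
  })
  expect_gte(mean(null_flags == 0), 0.9)

  # duplicated samples receive identical scores (no spurious single flag)
  m <- toy_matrix(12, 40, seed = 9)
  m[2, ] <- m[1, ]
  ann <- toy_annotation(m, n_cases = 0)
  sc <- pca_artifact_screen(m, ann)
  expect_equal(sc$scores[1, ], sc$scores[2, ], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("QC assembly and application drop exactly the flagged items", {
  spec <- small_spec(seed = 2)
  co <- generate_cohort(spec)

  # empty report is the identity
  empty <- qc_report()
  expect_identical(apply_qc(co$matrix, empty), co$matrix)

  pd <- generate_paired_draws(spec)
  frag <- filter_paired_draws(pd$matrix, pd$annotation)
  rep <- qc_report(paired = frag)
  out <- apply_qc(co$matrix, rep)
  expect_equal(ncol(out), ncol(co$matrix) - sum(frag$excluded))
  expect_length(intersect(colnames(out), rep$excluded_analytes$id), 0)
  expect_equal(nrow(out), nrow(co$matrix))

  # every exclusion carries a reason and a statistic
  expect_true(all(rep$excluded_analytes$reason == "PAIRED_DRAW"))
  expect_true(all(is.finite(rep$excluded_analytes$statistic)))

  # excluding one site's control samples removes that site downstream
  ann <- co$annotation
  sin_ids <- ann$sample_id[ann$site == "SYNTH-LIB"]
  rep2 <- qc_report()
  rep2$excluded_samples <- data.frame(id = sin_ids, reason = "PCA_ARTIFACT",
                                      statistic = 0)
  out2 <- apply_qc(co$matrix, rep2)
  expect_length(intersect(rownames(out2), sin_ids), 0)

  # long-format report file
  f <- tempfile()
  write_qc_report(rep, f)
  tab <- read.delim(f)
  expect_named(tab, c("id", "kind", "reason", "statistic"))
  expect_equal(nrow(tab), sum(frag$excluded))
})

test_that("QC never consults the case-control contrast and spares markers", {
  # the filters are computed from controls/pairs only: relabelling every
  # case as control changes nothing in the KS and paired fragments
  spec <- small_spec(seed = 13)
  co <- generate_cohort(spec)
  ann_blind <- co$annotation
  ann_blind$class_label[ann_blind$class_label == "CASE"] <- "CONTROL"
  ann_blind$stage <- NA_character_
  # (cases sit at case sites; keep site layout identical and compare the
  # control-site filter on the true control sites only)
  ks_a <- filter_ks_control_sets(co$matrix, co$annotation)
  ks_b <- filter_ks_control_sets(co$matrix[co$annotation$sample_id[
    co$annotation$class_label == "CONTROL"], ], co$annotation)
  expect_equal(ks_a$max_ks, ks_b$max_ks)

  # markers survive QC at the default study spec (mean loss <= 5%);
  # QC runs downstream of calibration + normalization, as in the pipeline
  loss <- sapply(1:10, function(s) {
    spec <- cohort_spec(seed = s)
    co <- generate_cohort(spec)
    pd <- generate_paired_draws(spec)
    m <- median_normalize(
      calibrate_plates(co$matrix, co$annotation)$calibrated)$normalized
    ks <- filter_ks_control_sets(m, co$annotation, min_site_n = 5)
    pr <- filter_paired_draws(pd$matrix, pd$annotation)
    pca <- pca_artifact_screen(m, co$annotation)
    rep <- qc_report(ks = ks, paired = pr, pca = pca)
    tm <- co$truth$true_marker_ids
    mean(tm %in% rep$excluded_analytes$id)
  })
  expect_lte(mean(loss), 0.05)
})
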