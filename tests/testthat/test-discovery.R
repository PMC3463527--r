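test_that("univariate screen: identical classes, nulls, and spiked power", {
  # identical case/control values: p = 1, fold change 1
  v <- c(100, 200, 300, 150)
  m <- matrix(rep(v, 2), ncol = 1,
              dimnames = list(paste0("S", 1:8), "A001"))
  m <- cbind(m, A002 = c(100, 110, 120, 130, 500, 510, 520, 530))
  ann <- toy_annotation(m, n_cases = 4)
  tab <- univariate_screen(m, ann)
  expect_equal(tab$t_p[1], 1)
  expect_equal(tab$ks_p[1], 1)
  expect_equal(tab$fold_change[1], 1)
  expect_equal(tab$direction[1], "FLAT")
  # direction consistent with the sign of the median log2 difference
  expect_equal(tab$direction[2], "DOWN")
  expect_lt(tab$t_p[2], 1e-4)

  # label-permuted null: p < 0.05 fraction near alpha
  frac <- sapply(1:10, function(s) {
    m <- toy_matrix(40, 500, seed = 200 + s)
    ann <- toy_annotation(m, n_cases = 20)  # labels independent of values
    mean(univariate_screen(m, ann)$t_p < 0.05)
  })
  expect_gte(mean(frac), 0.03)
  expect_lte(mean(frac), 0.07)

  # power: 1.0 log2 spike at n=60/60, noise 0.5 gives p < 1e-6
  hits <- sapply(1:10, function(s) {
    spec <- cohort_spec(n_cases = 60, n_controls = 60, n_analytes = 100,
                        n_true_markers = 5, n_weak_markers = 0,
                        stage_gradient = c(I = 1, II = 1, III = 1, IV = 1,
                                           UNKNOWN = 1),
                        site_shift_log2 = 0, site_affected_frac = 0,
                        n_artifact_analytes = 0, plate_bias_sd = 0, seed = s)
    co <- generate_cohort(spec)
    clin <- co$annotation$sample_id[
      co$annotation$class_label %in% c("CASE", "CONTROL")]
    tab <- univariate_screen(co$matrix[clin, ], co$annotation)
    mean(tab$t_p[tab$analyte_id %in% co$truth$true_marker_ids] < 1e-6)
  })
  expect_gte(mean(hits), 0.95)

  expect_error(univariate_screen(m[c(1, 5, 6), ], ann), ">= 2 samples")
})

test_that("BH q-values are monotone in p and selection respects the rule", {
  m <- toy_matrix(40, 200, seed = 44)
  ann <- toy_annotation(m, n_cases = 20)
  tab <- univariate_screen(m, ann)
  ord <- order(tab$t_p)
  expect_true(all(diff(tab$t_q[ord]) >= -1e-12))
  expect_true(all(tab$t_q >= tab$t_p - 1e-12))

  # threshold 0 selects nothing
  expect_length(select_candidates(tab, q_threshold = 0)$analyte_ids, 0)

  # all-null table at q < 0.01: BH keeps the candidate set (nearly) empty
  expect_lte(length(select_candidates(tab, 0.01)$analyte_ids), 2)

  # strong markers are selected on the study-scale spec
  rec <- sapply(1:10, function(s) {
    spec <- cohort_spec(seed = s)
    co <- generate_cohort(spec)
    clin <- co$annotation$sample_id[
      co$annotation$class_label %in% c("CASE", "CONTROL")]
    tab <- univariate_screen(co$matrix[clin, ], co$annotation)
    sel <- select_candidates(tab, 0.01, test = "t")$analyte_ids
    mean(co$truth$true_marker_ids %in% sel)
  })
  expect_gte(mean(rec), 0.9)
})

test_that("Gini ranking puts a perfect separator first among noise", {
  first <- sapply(1:20, function(s) {
    set.seed(s)
    n <- 60
    noise <- matrix(2 ^ rnorm(n * 63, 10, 1), nrow = n)
    sep <- 2 ^ c(rnorm(n / 2, 14, 0.2), rnorm(n / 2, 8, 0.2))
    m <- cbind(sep, noise)
    dimnames(m) <- list(sprintf("S%03d", 1:n), sprintf("A%03d", 1:64))
    ann <- toy_annotation(m, n_cases = n / 2)
    rk <- gini_rank(m, ann, colnames(m), ntree = 300, seed = s)
    # duplicating a noise candidate must not displace the separator
    m2 <- cbind(m, A065 = m[, "A002"])
    rk2 <- gini_rank(m2, ann, colnames(m2), ntree = 300, seed = s)
    (rk$analyte_id[1] == "A001") && (rk2$analyte_id[1] == "A001")
  })
  expect_gte(sum(first), 19)
})

test_that("Gini importances are exchangeable under the null", {
  # rank of a fixed analyte among all-noise candidates is ~uniform
  ranks <- sapply(1:30, function(s) {
    m <- toy_matrix(40, 20, seed = 300 + s)
    ann <- toy_annotation(m, n_cases = 20)
    rk <- gini_rank(m, ann, colnames(m), ntree = 200, seed = s)
    which(rk$analyte_id == "A001")
  })
  # mean rank of 20 candidates is 10.5; reject gross asymmetry only
  expect_gt(mean(ranks), 6.5)
  expect_lt(mean(ranks), 14.5)
  expect_gt(length(unique(ranks)), 5)
})

test_that("ranking and panel scan are deterministic and nested", {
  spec <- small_spec(seed = 6)
  co <- generate_cohort(spec)
  clin <- co$annotation$sample_id[
    co$annotation$class_label %in% c("CASE", "CONTROL")]
  m <- co$matrix[clin, ]
  tab <- univariate_screen(m, co$annotation)
  cand <- select_candidates(tab, 0.05, test = "either")
  expect_true(all(cand$analyte_ids %in% colnames(m)))

  rk1 <- gini_rank(m, co$annotation, cand, ntree = 300, seed = 11)
  rk2 <- gini_rank(m, co$annotation, cand, ntree = 300, seed = 11)
  expect_identical(rk1$analyte_id, rk2$analyte_id)
  expect_equal(rk1$gini, rk2$gini)
  expect_identical(sort(rk1$rank), seq_len(nrow(rk1)))
  expect_true(all(rk1$gini >= 0))
  expect_error(gini_rank(m, co$annotation, c("NOPE"), ntree = 10),
               "absent")

  sizes <- c(1, 3, 5, 10)
  scan <- panel_size_scan(m, co$annotation, rk1, sizes = sizes,
                          ntree = 300, seed = 3, force_k = 5)
  expect_equal(attr(scan, "chosen_k"), 5L)
  expect_identical(attr(scan, "panel"), rk1$analyte_id[1:5])
  expect_true(all(scan$oob_auc >= 0 & scan$oob_auc <= 1))

  # a single-size grid returns one row and that size
  one <- panel_size_scan(m, co$annotation, rk1, sizes = 10, ntree = 200,
                         seed = 3, force_k = NULL)
  expect_equal(nrow(one), 1)
  expect_equal(attr(one, "chosen_k"), 10L)
})

test_that("one informative candidate carries the scan; added noise cannot win", {
  set.seed(17)
  n <- 60
  sep <- 2 ^ c(rnorm(n / 2, 12.5, 0.5), rnorm(n / 2, 10, 0.5))
  noise <- matrix(2 ^ rnorm(n * 15, 10, 1), nrow = n)
  m <- cbind(sep, noise)
  dimnames(m) <- list(sprintf("S%03d", 1:n), sprintf("A%03d", 1:16))
  ann <- toy_annotation(m, n_cases = n / 2)
  rk <- gini_rank(m, ann, colnames(m), ntree = 500, seed = 2)
  scan <- panel_size_scan(m, ann, rk, sizes = c(1, 4, 16), ntree = 500,
                          seed = 2, force_k = NULL)
  auc1 <- scan$oob_auc[scan$k == 1]
  auc16 <- scan$oob_auc[scan$k == 16]
  se16 <- scan$auc_se[scan$k == 16]
  expect_gte(auc1, auc16 - se16)
})
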