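# brute-force AUC oracle: concordance probability with half credit for
# ties, by exhaustive pair counting
auc_brute <- function(scores, is_case) {
  x <- scores[is_case]; y <- scores[!is_case]
  s <- 0
  for (xi in x) for (yj in y)
    s <- s + (xi > yj) + 0.5 * (xi == yj)
  s / (length(x) * length(y))
}

test_that("Wald confidence intervals reproduce the reference study table", {
  ref <- reference_confusion_counts()

  tr <- confusion_metrics(ref$training)
  expect_equal(round(tr$estimate, 1), c(96.7, 91.7, 94.2))
  # training specificity 55/60: 91.7 (84.7-98.7)
  expect_equal(round(tr$lower[2], 1), 84.7)
  expect_equal(round(tr$upper[2], 1), 98.7)
  # training sensitivity 58/60: 96.7 (92.1-100.0), upper clipped
  expect_equal(round(tr$lower[1], 1), 92.1)
  expect_equal(tr$upper[1], 100)
  expect_equal(round(tr$lower[3], 1), 90.0)
  expect_equal(round(tr$upper[3], 1), 98.4)

  ve <- confusion_metrics(ref$verification)
  expect_equal(round(ve$estimate, 1), c(89.5, 95.0, 92.3))

  # degenerate 10/10 clips to 100 (100-100)
  deg <- confusion_metrics(confusion_counts(10, 0, 5, 0))
  expect_equal(deg$estimate[1], 100)
  expect_equal(deg$lower[1], 100)
  expect_equal(deg$upper[1], 100)

  # a zero denominator is an error
  expect_error(confusion_metrics(confusion_counts(0, 0, 5, 5)),
               "zero denominator")

  # interval width shrinks monotonically with n at fixed p
  widths <- sapply(c(10, 40, 160, 640), function(n) {
    cm <- confusion_metrics(confusion_counts(0.9 * n, 0.1 * n, 1, 0))
    cm$upper[1] - cm$lower[1]
  })
  expect_true(all(diff(widths) < 0))
})

test_that("cohort pooling sums counts rather than averaging percentages", {
  ref <- reference_confusion_counts()
  pooled <- pool_cohorts(ref)
  expect_equal(pooled$tp, 109); expect_equal(pooled$fn, 8)
  expect_equal(pooled$tn, 129); expect_equal(pooled$fp, 13)
  pm <- confusion_metrics(pooled)
  expect_equal(round(pm$estimate, 1), c(93.2, 90.8, 91.9))
  expect_equal(round(pm$lower, 1), c(88.6, 86.1, 88.6))
  expect_equal(round(pm$upper, 1), c(97.7, 95.6, 95.2))

  # guard: with unequal cohorts, pooling differs from the mean of rates
  a <- confusion_counts(9, 1, 9, 1)     # 90% sens on n=10
  b <- confusion_counts(50, 50, 50, 50) # 50% sens on n=100
  p <- confusion_metrics(pool_cohorts(list(a, b)))
  expect_equal(p$estimate[1], 100 * 59 / 110)
  expect_false(isTRUE(all.equal(p$estimate[1], 70)))

  # single-cohort pooling is the identity
  one <- pool_cohorts(list(a))
  expect_equal(one$tp, a$tp); expect_equal(one$fp, a$fp)
})

test_that("stage-stratified detection reproduces the reference pooled rates", {
  st <- reference_stage_detection()
  pooled <- aggregate(cbind(detected, total) ~ stage, st, sum)
  pooled$pct <- 100 * pooled$detected / pooled$total
  expect_equal(round(pooled$pct[pooled$stage == "I"]), 77)     # 10/13
  expect_equal(round(pooled$pct[pooled$stage == "II"]), 93)    # 25/27
  expect_equal(round(pooled$pct[pooled$stage == "III"]), 96)
  expect_equal(round(pooled$pct[pooled$stage == "IV"]), 96)
  early <- pooled[pooled$stage %in% c("I", "II"), ]
  expect_equal(round(100 * sum(early$detected) / sum(early$total)), 88)

  # stage_sensitivity tallies labels against case stages
  scores <- data.frame(sample_id = paste0("S", 1:6),
                       score = c(0.9, 0.8, 0.2, 0.9, 0.1, 0.3),
                       label = c("CASE", "CASE", "CONTROL", "CASE",
                                 "CONTROL", "CONTROL"))
  class(scores) <- c("score_set", "data.frame")
  ann <- data.frame(sample_id = paste0("S", 1:6),
                    class_label = c(rep("CASE", 4), "CONTROL", "CONTROL"),
                    site = "SYNTH-KAR", draw_type = NA, subject_id = NA,
                    plate_id = "P01",
                    stage = c("I", "I", "II", "III", NA, NA),
                    histology = c(rep("UNKNOWN", 4), NA, NA),
                    assay_version = "V1")
  tab <- stage_sensitivity(scores, ann)
  expect_equal(tab$detected[tab$stage == "I"], 2)
  expect_equal(tab$total[tab$stage == "I"], 2)
  expect_equal(tab$detected[tab$stage == "II"], 0)
  expect_equal(tab$total[tab$stage == "IV"], 0)   # empty stratum: 0/0
  expect_true(is.na(tab$pct[tab$stage == "IV"]))

  # pooling stage tables adds strata across cohorts
  p2 <- pool_stage_tables(list(tab, tab))
  expect_equal(p2$detected[p2$stage == "I"], 4)
})

test_that("ROC/AUC equals brute-force pair counting on random instances", {
  # fixed worked example
  sc <- c(0.1, 0.4, 0.35, 0.8); lab <- c(FALSE, TRUE, FALSE, TRUE)
  r <- roc_auc(sc, lab)
  expect_equal(r$auc, auc_brute(sc, lab))

  set.seed(19)
  for (i in 1:40) {
    n1 <- sample(2:25, 1); n0 <- sample(2:25, 1)
    sc <- if (i %% 2) c(rnorm(n1, 1), rnorm(n0))
          else sample(seq(0, 1, 0.1), n1 + n0, replace = TRUE)  # heavy ties
    lab <- c(rep(TRUE, n1), rep(FALSE, n0))
    r <- roc_auc(sc, lab)
    expect_equal(r$auc, auc_brute(sc, lab))
    # the stored points trapezoid back to the same AUC
    pts <- r$points
    trap <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-12)
    # curve is monotone from (0,0) to (1,1)
    expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
    expect_equal(c(pts$fpr[1], pts$tpr[1]), c(0, 0))
    expect_equal(c(pts$fpr[nrow(pts)], pts$tpr[nrow(pts)]), c(1, 1))
  }

  # boundary cases
  expect_equal(roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  set.seed(4)
  big <- roc_auc(rnorm(2000), rep(c(TRUE, FALSE), 1000))
  expect_lt(abs(big$auc - 0.5), 0.05)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("DeLong intervals agree with an independent implementation", {
  set.seed(23)
  for (i in 1:5) {
    n1 <- 30; n0 <- 40
    sc <- c(rnorm(n1, 1), rnorm(n0))
    lab <- c(rep(TRUE, n1), rep(FALSE, n0))
    r <- roc_auc(sc, lab, ci_method = "delong")
    pr <- pROC::roc(response = lab, predictor = sc, quiet = TRUE,
                    direction = "<")
    ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
    expect_equal(r$auc, as.numeric(pROC::auc(pr)))
    expect_equal(c(r$ci_lower, r$ci_upper), ci[c(1, 3)], tolerance = 1e-6)
  }
  # bootstrap CI covers the point estimate and is reproducible
  sc <- c(rnorm(25, 1), rnorm(25)); lab <- rep(c(TRUE, FALSE), each = 25)
  b1 <- roc_auc(sc, lab, ci_method = "bootstrap", boot_n = 500, seed = 2)
  b2 <- roc_auc(sc, lab, ci_method = "bootstrap", boot_n = 500, seed = 2)
  expect_equal(b1$ci_lower, b2$ci_lower)
  expect_lte(b1$ci_lower, b1$auc); expect_gte(b1$ci_upper, b1$auc)
})

test_that("operating points maximize sensitivity under the constraint", {
  sc <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.2)
  lab <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  r <- roc_auc(sc, lab)

  # exhaustive cutoff enumeration oracle
  brute_best <- function(s_min) {
    cand <- unique(c(Inf, sc, -Inf))
    best <- NULL
    for (t in cand) {
      se <- mean(sc[lab] >= t); sp <- mean(sc[!lab] < t)
      if (sp >= s_min && (is.null(best) || se > best[1] ||
                          (se == best[1] && sp > best[2])))
        best <- c(se, sp)
    }
    best
  }
  for (s in c(0, 0.5, 0.75, 1)) {
    op <- operating_point(r, s)
    oracle <- brute_best(s)
    expect_equal(op$sensitivity, oracle[1])
    expect_equal(op$specificity, oracle[2])
  }
  expect_equal(operating_point(r, 0)$sensitivity, 1)
  expect_error(operating_point(r, 1.2), "unsatisfiable")
})

test_that("screening estimates reproduce the reference arithmetic", {
  est <- screening_estimates(0.932, 0.908, prevalence = 0.014)
  expect_equal(round(100 * est$ppv, 1), 12.6)
  expect_equal(round(100 * est$npv, 1), 99.9)
  expect_equal(round(100 * est$population_accuracy, 1), 90.8)

  # Bayes identity: PPV * P(test positive) = sensitivity * prevalence
  se <- 0.932; sp <- 0.908; pi <- 0.014
  test_pos <- se * pi + (1 - sp) * (1 - pi)
  expect_equal(est$ppv * test_pos, se * pi, tolerance = 1e-12)

  # boundary prevalences return the documented limits
  expect_equal(screening_estimates(0.9, 0.9, 0)$ppv, 0)
  expect_equal(screening_estimates(0.9, 0.9, 0)$npv, 1)
  expect_equal(screening_estimates(0.9, 0.9, 1)$ppv, 1)
  expect_equal(screening_estimates(0.9, 0.9, 1)$population_accuracy, 0.9)
  expect_error(screening_estimates(0, 0.9, 0.5))
})
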