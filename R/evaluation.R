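# Diagnostic evaluation statistics: confusion metrics with Wald
# confidence intervals, cohort pooling on counts, stage-stratified
# sensitivity, empirical ROC curves with AUC and DeLong or bootstrap
# intervals, alternative operating points, and prevalence-adjusted
# screening estimates.

#' Construct validated confusion counts
#'
#' @param tp,fn,tn,fp Non-negative integers; `tp + fn` cases and
#'   `tn + fp` controls.
#' @param cohort Optional cohort tag.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fn, tn, fp, cohort = "") {
  v <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(v < 0) || any(v != round(v)))
    stop("confusion counts must be non-negative integers")
  out <- as.list(v)
  out$cohort <- cohort
  class(out) <- "confusion_counts"
  out
}

#' Tally confusion counts from a score set and annotation
#'
#' @param scores A `score_set` from [predict.panel_model()].
#' @param ann Annotation supplying the true class labels.
#' @param cohort Optional cohort tag.
#' @return A [confusion_counts()].
#' @export
confusion_from_scores <- function(scores, ann, cohort = "") {
  idx <- match(scores$sample_id, ann$sample_id)
  if (anyNA(idx)) stop("unannotated scored sample(s)")
  truth <- ann$class_label[idx]
  keep <- truth %in% c("CASE", "CONTROL")
  truth <- truth[keep]; pred <- scores$label[keep]
  confusion_counts(tp = sum(truth == "CASE" & pred == "CASE"),
                   fn = sum(truth == "CASE" & pred == "CONTROL"),
                   tn = sum(truth == "CONTROL" & pred == "CONTROL"),
                   fp = sum(truth == "CONTROL" & pred == "CASE"),
                   cohort = cohort)
}

wald_ci_pct <- function(k, n, level) {
  if (n < 1L) stop("zero denominator in confusion metric")
  p <- k / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(estimate = 100 * p,
    lower = max(0, 100 * (p - half)),
    upper = min(100, 100 * (p + half)))
}

#' Sensitivity, specificity, and accuracy with Wald intervals
#'
#' Each metric is reported as a percentage with a normal-approximation
#' (Wald) confidence interval `p +/- z * sqrt(p(1-p)/n)`, clipped to
#' `[0, 100]`. Full precision is retained; round only for display.
#'
#' @param counts A [confusion_counts()].
#' @param ci_level Confidence level (default 0.95).
#' @return Data.frame with rows sensitivity/specificity/accuracy and
#'   columns `estimate`, `lower`, `upper`, `n`.
#' @export
confusion_metrics <- function(counts, ci_level = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  n_case <- counts$tp + counts$fn
  n_ctrl <- counts$tn + counts$fp
  rows <- rbind(
    sensitivity = c(wald_ci_pct(counts$tp, n_case, ci_level), n = n_case),
    specificity = c(wald_ci_pct(counts$tn, n_ctrl, ci_level), n = n_ctrl),
    accuracy = c(wald_ci_pct(counts$tp + counts$tn, n_case + n_ctrl,
                             ci_level), n = n_case + n_ctrl))
  out <- data.frame(metric = rownames(rows), rows, row.names = NULL)
  out
}

#' Pool confusion counts across cohorts
#'
#' Element-wise sum of the counts; pooled metrics are then computed from
#' the summed counts, never by averaging cohort percentages.
#'
#' @param counts_list List of [confusion_counts()].
#' @param cohort Tag for the pooled record (default `"combined"`).
#' @return A [confusion_counts()].
#' @export
pool_cohorts <- function(counts_list, cohort = "combined") {
  if (inherits(counts_list, "confusion_counts"))
    counts_list <- list(counts_list)
  stopifnot(length(counts_list) >= 1L,
            all(vapply(counts_list, inherits, logical(1L), "confusion_counts")))
  s <- function(f) sum(vapply(counts_list, `[[`, numeric(1L), f))
  confusion_counts(s("tp"), s("fn"), s("tn"), s("fp"), cohort = cohort)
}

#' Stage-stratified detection table
#'
#' Among true cases, counts detected (predicted positive) per pathologic
#' stage. Strata with no cases are reported as 0/0 with `NA` percentage.
#'
#' @param scores A `score_set`.
#' @param ann Annotation with per-case stages.
#' @return Data.frame `stage`, `detected`, `total`, `pct`.
#' @export
stage_sensitivity <- function(scores, ann) {
  idx <- match(scores$sample_id, ann$sample_id)
  if (anyNA(idx)) stop("unannotated scored sample(s)")
  is_case <- ann$class_label[idx] == "CASE"
  stage <- ann$stage[idx]
  detected <- scores$label == "CASE"
  out <- do.call(rbind, lapply(STAGES, function(s) {
    sel <- is_case & !is.na(stage) & stage == s
    data.frame(stage = s, detected = sum(detected & sel), total = sum(sel))
  }))
  out$pct <- ifelse(out$total > 0, 100 * out$detected / out$total, NA_real_)
  out
}

#' Pool stage detection tables across cohorts
#'
#' @param tables List of [stage_sensitivity()] tables.
#' @return Pooled table in the same format.
#' @export
pool_stage_tables <- function(tables) {
  out <- tables[[1L]][, c("stage", "detected", "total")]
  for (t in tables[-1L]) {
    stopifnot(identical(t$stage, out$stage))
    out$detected <- out$detected + t$detected
    out$total <- out$total + t$total
  }
  out$pct <- ifelse(out$total > 0, 100 * out$detected / out$total, NA_real_)
  out
}

# DeLong variance components of the empirical AUC
delong_se <- function(x, y) {
  # x: case scores, y: control scores
  v10 <- vapply(x, function(xi) mean((y < xi) + 0.5 * (y == xi)), numeric(1L))
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1L))
  s10 <- if (length(x) > 1L) stats::var(v10) else 0
  s01 <- if (length(y) > 1L) stats::var(v01) else 0
  sqrt(s10 / length(x) + s01 / length(y))
}

#' Empirical ROC curve with AUC and confidence interval
#'
#' The curve is evaluated at every distinct score cutoff (predicted
#' positive iff score >= cutoff), running from (0, 0) to (1, 1). The AUC
#' equals the Mann-Whitney concordance probability with half credit for
#' ties, which is identical to the trapezoidal area of the stored
#' points. The confidence interval uses DeLong's method by default, or a
#' stratified bootstrap.
#'
#' @param scores Numeric scores (higher = more disease-like), or a
#'   `score_set`.
#' @param is_case Logical vector of true case status (required when
#'   `scores` is numeric), or an annotation data.frame when `scores` is a
#'   `score_set`.
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param level Confidence level (default 0.95).
#' @param boot_n Bootstrap replicates (default 2000).
#' @param seed Bootstrap seed.
#' @return A `roc_curve`: list with `points` (`fpr`, `tpr`, `cutoff`),
#'   `auc`, `ci_lower`, `ci_upper`; attribute `auc_se` holds the DeLong
#'   standard error.
#' @export
roc_auc <- function(scores, is_case, ci_method = c("delong", "bootstrap"),
                    level = 0.95, boot_n = 2000L, seed = 1L) {
  ci_method <- match.arg(ci_method)
  if (inherits(scores, "score_set")) {
    ann <- is_case
    idx <- match(scores$sample_id, ann$sample_id)
    is_case <- ann$class_label[idx] == "CASE"
    keep <- ann$class_label[idx] %in% c("CASE", "CONTROL")
    scores <- scores$score[keep]; is_case <- is_case[keep]
  }
  stopifnot(length(scores) == length(is_case))
  if (!any(is_case) || all(is_case))
    stop("ROC requires both classes present")
  x <- scores[is_case]; y <- scores[!is_case]

  cut <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(cut, function(t) mean(x >= t), numeric(1L))
  fpr <- vapply(cut, function(t) mean(y >= t), numeric(1L))
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                    cutoff = c(Inf, cut, -Inf))

  r <- rank(c(x, y))
  auc <- (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
    (length(x) * length(y))
  se <- delong_se(x, y)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (ci_method == "delong") {
    lo <- max(0, auc - z * se); hi <- min(1, auc + z * se)
  } else {
    boots <- with_seed(seed, vapply(seq_len(boot_n), function(b) {
      xb <- sample(x, replace = TRUE); yb <- sample(y, replace = TRUE)
      rb <- rank(c(xb, yb))
      (sum(rb[seq_along(xb)]) - length(xb) * (length(xb) + 1) / 2) /
        (length(xb) * length(yb))
    }, numeric(1L)))
    qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2))
    lo <- unname(qs[1L]); hi <- unname(qs[2L])
  }
  out <- list(points = pts, auc = auc, ci_lower = lo, ci_upper = hi,
              ci_method = ci_method, level = level)
  attr(out, "auc_se") <- se
  class(out) <- "roc_curve"
  out
}

#' Operating point under a specificity constraint
#'
#' Among stored cutoffs whose specificity (1 - FPR) meets the
#' constraint, returns the one maximizing sensitivity; ties resolved
#' toward the higher specificity.
#'
#' @param roc A [roc_auc()] result.
#' @param min_specificity Required specificity in `[0, 1]`.
#' @return List with `cutoff`, `sensitivity`, `specificity`.
#' @export
operating_point <- function(roc, min_specificity) {
  stopifnot(inherits(roc, "roc_curve"))
  if (min_specificity > 1)
    stop("unsatisfiable constraint: specificity cannot exceed 1")
  pts <- roc$points
  ok <- which(1 - pts$fpr >= min_specificity)
  best <- ok[pts$tpr[ok] == max(pts$tpr[ok])]
  pick <- best[which.min(pts$fpr[best])]
  list(cutoff = pts$cutoff[pick],
       sensitivity = pts$tpr[pick],
       specificity = 1 - pts$fpr[pick])
}

#' Prevalence-adjusted screening estimates
#'
#' Bayes-rule post-test probabilities at a stated disease prevalence:
#' `PPV = se*pi / (se*pi + (1-sp)(1-pi))`, `NPV = sp(1-pi) / (sp(1-pi) +
#' (1-se)pi)`, and population accuracy `se*pi + sp(1-pi)`. Boundary
#' prevalences 0 and 1 return the documented limit values.
#'
#' @param sensitivity,specificity Proportions in (0, 1]; a perfect
#'   sensitivity or specificity is legal (the Bayes formulas remain
#'   well-defined), a zero one is not.
#' @param prevalence Disease prevalence in `[0, 1]`; default 0.014, a
#'   screen-detected malignancy rate reported for asbestos-exposed
#'   surveillance populations.
#' @return A `screening_estimates` list: `prevalence`, `ppv`, `npv`,
#'   `population_accuracy` (proportions in `[0, 1]`).
#' @export
screening_estimates <- function(sensitivity, specificity,
                                prevalence = 0.014) {
  stopifnot(sensitivity > 0, sensitivity <= 1,
            specificity > 0, specificity <= 1,
            prevalence >= 0, prevalence <= 1)
  se <- sensitivity; sp <- specificity; pi <- prevalence
  if (pi == 0) {
    out <- list(prevalence = 0, ppv = 0, npv = 1, population_accuracy = sp)
  } else if (pi == 1) {
    out <- list(prevalence = 1, ppv = 1, npv = 0, population_accuracy = se)
  } else {
    out <- list(
      prevalence = pi,
      ppv = se * pi / (se * pi + (1 - sp) * (1 - pi)),
      npv = sp * (1 - pi) / (sp * (1 - pi) + (1 - se) * pi),
      population_accuracy = se * pi + sp * (1 - pi))
  }
  class(out) <- "screening_estimates"
  out
}

#' Reported classification counts of the reference MM surveillance study
#'
#' The published per-cohort confusion counts and per-stage detection
#' counts of the multi-center serum MM surveillance study this pipeline
#' mirrors (117 cases / 142 asbestos-exposed controls across training,
#' blinded verification, and blinded validation cohorts). Shipped as
#' plain TSV inputs; used by the worked examples and the evaluation-
#' statistics acceptance checks.
#'
#' @return `reference_confusion_counts()`: list of [confusion_counts()]
#'   keyed by cohort. `reference_stage_detection()`: data.frame `stage`,
#'   `cohort`, `detected`, `total`.
#' @export
reference_confusion_counts <- function() {
  path <- system.file("extdata", "mm_study_confusion_counts.tsv",
                      package = "mesopanel", mustWork = TRUE)
  df <- utils::read.delim(path)
  out <- lapply(seq_len(nrow(df)), function(i) {
    confusion_counts(df$tp[i], df$fn[i], df$tn[i], df$fp[i],
                     cohort = df$cohort[i])
  })
  stats::setNames(out, df$cohort)
}

#' @rdname reference_confusion_counts
#' @export
reference_stage_detection <- function() {
  path <- system.file("extdata", "mm_study_stage_detection.tsv",
                      package = "mesopanel", mustWork = TRUE)
  utils::read.delim(path, colClasses = c("character", "character",
                                         "integer", "integer"))
}
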