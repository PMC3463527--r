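# Candidate marker discovery: univariate screening with multiplicity
# control, Gini-importance ranking from a single random forest, and a
# nested panel-size scan. These operations must only ever see training
# samples; the pipeline audits that contract.

#' Univariate case-control screen of all analytes
#'
#' Per analyte, a Welch unequal-variance t-test and a two-sample
#' Kolmogorov-Smirnov test on log2 values, Benjamini-Hochberg adjusted
#' q-values per test, the direction of regulation from the sign of the
#' median log2 difference, and the fold change (median case RFU / median
#' control RFU).
#'
#' @param m RFU matrix (QC applied).
#' @param ann Annotation; requires at least 2 samples per class.
#' @return A `univariate_table` data.frame with columns `analyte_id`,
#'   `t_p`, `t_q`, `ks_p`, `ks_q`, `direction` (`UP`/`DOWN`/`FLAT`),
#'   `fold_change`, `median_log2_diff`.
#' @export
univariate_screen <- function(m, ann) {
  validate_rfu_matrix(m)
  validate_annotation(ann)
  idx <- match(rownames(m), ann$sample_id)
  if (anyNA(idx)) stop("unannotated sample(s)")
  lab <- ann$class_label[idx]
  case <- lab == "CASE"; ctrl <- lab == "CONTROL"
  if (sum(case) < 2L || sum(ctrl) < 2L)
    stop("univariate screen requires >= 2 samples per class")
  lv <- log2(m)
  x <- lv[case, , drop = FALSE]
  y <- lv[ctrl, , drop = FALSE]
  res <- vapply(seq_len(ncol(lv)), function(j) {
    xv <- x[, j]; yv <- y[, j]
    if (stats::sd(xv) == 0 && stats::sd(yv) == 0 && xv[1L] == yv[1L]) {
      tp <- 1; kp <- 1
    } else {
      tp <- tryCatch(stats::t.test(xv, yv)$p.value, error = function(e) 1)
      kp <- suppressWarnings(stats::ks.test(xv, yv)$p.value)
    }
    c(tp, kp, stats::median(xv) - stats::median(yv))
  }, numeric(3L))
  md <- res[3L, ]
  tab <- data.frame(
    analyte_id = colnames(m),
    t_p = res[1L, ],
    t_q = stats::p.adjust(res[1L, ], method = "BH"),
    ks_p = res[2L, ],
    ks_q = stats::p.adjust(res[2L, ], method = "BH"),
    direction = ifelse(md > 0, "UP", ifelse(md < 0, "DOWN", "FLAT")),
    fold_change = 2 ^ md,
    median_log2_diff = md,
    stringsAsFactors = FALSE)
  class(tab) <- c("univariate_table", "data.frame")
  tab
}

#' Select candidate markers from a univariate table
#'
#' Analytes with adjusted q strictly below the threshold under the chosen
#' test (`t`, `ks`, or `either`). The selection rule is recorded with the
#' result for provenance.
#'
#' @param table A [univariate_screen()] result.
#' @param q_threshold FDR threshold (default 0.01).
#' @param test Which test gates selection (default `"t"`).
#' @return A `candidate_set`: list with sorted `analyte_ids` and `rule`.
#' @export
select_candidates <- function(table, q_threshold = 0.01,
                              test = c("t", "ks", "either")) {
  test <- match.arg(test)
  stopifnot(inherits(table, "univariate_table"))
  sel <- switch(test,
                t = table$t_q < q_threshold,
                ks = table$ks_q < q_threshold,
                either = table$t_q < q_threshold | table$ks_q < q_threshold)
  out <- list(analyte_ids = sort(table$analyte_id[sel]),
              rule = list(test = test, q_threshold = q_threshold))
  class(out) <- "candidate_set"
  out
}

# shared forest fit on log2 candidate values; x/y interface, so no
# formula environments are captured in the model object
fit_forest <- function(m, ann, analytes, ntree, mtry = NULL, seed = 1L) {
  missing_a <- setdiff(analytes, colnames(m))
  if (length(missing_a))
    stop("analyte(s) absent from matrix: ", paste(missing_a, collapse = ", "))
  idx <- match(rownames(m), ann$sample_id)
  lab <- ann$class_label[idx]
  keep <- lab %in% c("CASE", "CONTROL")
  x <- log2(m[keep, analytes, drop = FALSE])
  y <- factor(lab[keep], levels = c("CONTROL", "CASE"))
  if (nlevels(droplevels(y)) < 2L)
    stop("training labels contain a single class")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  with_seed(seed, randomForest::randomForest(
    x = x, y = y, ntree = ntree, mtry = mtry, importance = FALSE))
}

#' Rank candidate markers by random-forest Gini importance
#'
#' Builds one random forest (default 1000 trees, bootstrap per tree, Gini
#' split criterion, sqrt(p) features per split) on log2 values of all
#' candidates using training samples, and ranks candidates by mean
#' decrease in Gini impurity. A single ranking from a single forest is
#' used rather than stepwise reselection.
#'
#' @param m RFU matrix restricted to training samples.
#' @param ann Annotation.
#' @param candidates A [select_candidates()] result or character vector.
#' @param ntree Number of trees (default 1000).
#' @param mtry Features per split; default `floor(sqrt(p))`.
#' @param seed Integer seed.
#' @return An `importance_ranking`: data.frame `analyte_id`, `gini`,
#'   `rank`, with attributes `oob_error` and `seed`.
#' @export
gini_rank <- function(m, ann, candidates, ntree = 1000L, mtry = NULL,
                      seed = 1L) {
  ids <- if (inherits(candidates, "candidate_set")) candidates$analyte_ids
         else candidates
  if (!length(ids)) stop("candidate set is empty")
  rf <- fit_forest(m, ann, ids, ntree = ntree, mtry = mtry, seed = seed)
  gini <- rf$importance[, "MeanDecreaseGini"]
  ord <- order(-gini, names(gini))  # ties broken by analyte id
  rk <- data.frame(analyte_id = names(gini)[ord],
                   gini = unname(gini[ord]),
                   rank = seq_along(gini),
                   stringsAsFactors = FALSE)
  attr(rk, "oob_error") <- unname(rf$err.rate[ntree, "OOB"])
  attr(rk, "seed") <- as.integer(seed)
  class(rk) <- c("importance_ranking", "data.frame")
  rk
}

#' Scan nested panel sizes by out-of-bag AUC
#'
#' For each size `k` in the grid, trains a forest on the top-`k` analytes
#' of a fixed importance ranking (panels are nested by construction) and
#' records the out-of-bag AUC with its DeLong standard error. The chosen
#' size is `force_k` when given (default 13); otherwise the smallest `k`
#' whose AUC is within one standard error of the maximum.
#'
#' @param m RFU matrix restricted to training samples.
#' @param ann Annotation.
#' @param ranking An [gini_rank()] result.
#' @param sizes Integer grid of panel sizes.
#' @param ntree Trees per forest (default 1000).
#' @param seed Integer seed.
#' @param force_k Hard panel-size override (default 13; set `NULL` to use
#'   the one-standard-error rule).
#' @return A `panel_scan`: data.frame `k`, `oob_auc`, `auc_se`, with
#'   attributes `chosen_k` and `panel` (the top-`chosen_k` analytes).
#' @export
panel_size_scan <- function(m, ann, ranking, sizes = c(1, 2, 3, 5, 8, 13,
                                                       21, 34, 51, 64),
                            ntree = 1000L, seed = 1L, force_k = 13L) {
  stopifnot(inherits(ranking, "importance_ranking"))
  sizes <- sort(unique(as.integer(sizes)))
  if (!is.null(force_k)) sizes <- sort(unique(c(sizes, as.integer(force_k))))
  sizes <- sizes[sizes >= 1L & sizes <= nrow(ranking)]
  if (!length(sizes)) stop("no usable panel sizes <= |ranking|")
  idx <- match(rownames(m), ann$sample_id)
  lab <- ann$class_label[idx]
  is_case <- lab[lab %in% c("CASE", "CONTROL")] == "CASE"
  res <- lapply(seq_along(sizes), function(i) {
    k <- sizes[i]
    rf <- fit_forest(m, ann, ranking$analyte_id[seq_len(k)], ntree = ntree,
                     seed = substream_seed(seed, paste0("scan", k)))
    sc <- rf$votes[, "CASE"]
    roc <- roc_auc(sc, is_case)
    c(auc = roc$auc, se = attr(roc, "auc_se"))
  })
  scan <- data.frame(k = sizes,
                     oob_auc = vapply(res, `[[`, numeric(1L), "auc"),
                     auc_se = vapply(res, `[[`, numeric(1L), "se"))
  chosen <- if (!is.null(force_k) && as.integer(force_k) %in% sizes) {
    as.integer(force_k)
  } else {
    best <- which.max(scan$oob_auc)
    floor_auc <- scan$oob_auc[best] - scan$auc_se[best]
    min(scan$k[scan$oob_auc >= floor_auc])
  }
  attr(scan, "chosen_k") <- chosen
  attr(scan, "panel") <- ranking$analyte_id[seq_len(chosen)]
  class(scan) <- c("panel_scan", "data.frame")
  scan
}
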