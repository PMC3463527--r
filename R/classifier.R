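# Fixed-panel random-forest classifier with a pre-specified decision
# threshold, blinded prediction, and assay-version bridging.
#
# The decision threshold is fixed at training time from out-of-bag
# scores (never resubstitution) and is immutable thereafter; prediction
# reads only the RFU matrix, so there is no access path from scoring to
# class labels — that interface is what enforces the blinding contract.

#' Train a fixed-panel random-forest disease classifier
#'
#' Fits a random forest on log2 values of the panel analytes and fixes
#' the decision threshold: under the `youden` rule, the out-of-bag score
#' cutoff maximizing sensitivity + specificity, ties broken first by
#' minimal |sensitivity - specificity| (equal weight to both error
#' types), then by the lower cutoff; under `fixed`, the supplied value.
#'
#' @param m RFU matrix of training samples.
#' @param ann Annotation.
#' @param panel Character vector of panel analyte ids.
#' @param ntree Trees (default 1000).
#' @param threshold_rule `"youden"` (default) or `"fixed"`.
#' @param fixed_threshold Threshold in (0, 1) when `threshold_rule =
#'   "fixed"`.
#' @param seed Integer seed.
#' @param assay_version Version label stored with the model.
#' @return A `panel_model`: list with `panel`, `forest`, `threshold`,
#'   `threshold_rule`, `oob_scores`, `oob_sensitivity`,
#'   `oob_specificity`, `training_ids`, `training_hash`, `seed`,
#'   `assay_version`.
#' @export
train_panel_model <- function(m, ann, panel, ntree = 1000L,
                              threshold_rule = c("youden", "fixed"),
                              fixed_threshold = NULL, seed = 1L,
                              assay_version = "V1") {
  threshold_rule <- match.arg(threshold_rule)
  rf <- fit_forest(m, ann, panel, ntree = ntree, seed = seed)
  oob <- rf$votes[, "CASE"]
  truth <- rf$y == "CASE"

  if (threshold_rule == "fixed") {
    if (is.null(fixed_threshold) || fixed_threshold <= 0 || fixed_threshold >= 1)
      stop("threshold_rule 'fixed' requires fixed_threshold in (0, 1)")
    thr <- fixed_threshold
  } else {
    cand <- sort(unique(oob))
    sens <- vapply(cand, function(t) mean(oob[truth] >= t), numeric(1L))
    spec <- vapply(cand, function(t) mean(oob[!truth] < t), numeric(1L))
    j <- sens + spec
    best <- which(j == max(j))
    if (length(best) > 1L) {
      bal <- abs(sens[best] - spec[best])
      best <- best[bal == min(bal)]
    }
    thr <- min(cand[best])
  }
  model <- list(panel = panel,
                forest = rf,
                threshold = thr,
                threshold_rule = threshold_rule,
                oob_scores = oob,
                oob_sensitivity = mean(oob[truth] >= thr),
                oob_specificity = mean(oob[!truth] < thr),
                training_ids = sort(names(oob)),
                training_hash = content_hash(sort(names(oob))),
                seed = as.integer(seed),
                assay_version = assay_version)
  class(model) <- "panel_model"
  model
}

#' Score samples with a fixed panel model
#'
#' Deterministic given the model: emits the disease probability (fraction
#' of trees voting for disease) and the thresholded label for every
#' sample. Never reads annotations; a missing panel analyte is a hard
#' error, never silently imputed.
#'
#' @param object A `panel_model`.
#' @param m RFU matrix to score.
#' @param ... Unused.
#' @return A `score_set` data.frame: `sample_id`, `score`, `label`
#'   (`"CASE"`/`"CONTROL"`, positive iff score >= threshold), with the
#'   threshold as an attribute.
#' @export
predict.panel_model <- function(object, m, ...) {
  validate_rfu_matrix(m)
  missing_a <- setdiff(object$panel, colnames(m))
  if (length(missing_a))
    stop("panel analyte(s) absent from matrix: ",
         paste(missing_a, collapse = ", "))
  x <- log2(m[, object$panel, drop = FALSE])
  votes <- stats::predict(object$forest, newdata = x, type = "vote",
                          norm.votes = TRUE)
  sc <- votes[, "CASE"]
  out <- data.frame(sample_id = rownames(m),
                    score = unname(sc),
                    label = ifelse(sc >= object$threshold, "CASE", "CONTROL"),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- object$threshold
  class(out) <- c("score_set", "data.frame")
  out
}

#' Save / load a panel model archive
#'
#' Self-describing single-file archive; `load_panel_model()` restores a
#' model whose predictions are bit-identical to the saved one's.
#'
#' @param model A `panel_model`.
#' @param path Archive path.
#' @return `path` (save), or the restored `panel_model` (load).
#' @export
save_panel_model <- function(model, path) {
  stopifnot(inherits(model, "panel_model"))
  saveRDS(model, path, version = 3L)
  invisible(path)
}

#' @rdname save_panel_model
#' @export
load_panel_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "panel_model"))
  model
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive their mean rank).
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("spearman_cor requires paired vectors of equal length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearman correlation undefined for constant input")
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

#' Bridge a panel model across assay versions
#'
#' Retrains the same panel on the new-version measurements of the
#' bridging samples (the training samples present in both versions) and
#' reports the Spearman rank correlation between the two models'
#' out-of-bag scores on the shared samples. A correlation below
#' `correlation_floor` raises the `flag`.
#'
#' @param model_v1 The original `panel_model`.
#' @param m_v2 RFU matrix in the new assay version, containing the
#'   bridging samples and the full panel.
#' @param ann Annotation covering the bridging samples.
#' @param seed Retraining seed.
#' @param correlation_floor Minimum acceptable Spearman correlation
#'   (default 0.9).
#' @param assay_version Version label for the retrained model.
#' @return A `bridge_result`: list with `model` (retrained), `shared_ids`,
#'   `spearman`, `flag`.
#' @export
bridge_versions <- function(model_v1, m_v2, ann, seed = 1L,
                            correlation_floor = 0.9,
                            assay_version = "V2") {
  stopifnot(inherits(model_v1, "panel_model"))
  shared <- intersect(model_v1$training_ids, rownames(m_v2))
  if (!length(shared)) stop("no shared bridging samples between versions")
  model_v2 <- train_panel_model(
    m_v2[shared, , drop = FALSE], ann, panel = model_v1$panel,
    ntree = model_v1$forest$ntree, threshold_rule = model_v1$threshold_rule,
    fixed_threshold = if (model_v1$threshold_rule == "fixed")
      model_v1$threshold else NULL,
    seed = seed, assay_version = assay_version)
  rho <- spearman_cor(model_v1$oob_scores[shared],
                      model_v2$oob_scores[shared])
  res <- list(model = model_v2, shared_ids = shared, spearman = rho,
              flag = rho < correlation_floor,
              correlation_floor = correlation_floor)
  class(res) <- "bridge_result"
  res
}
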