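# Preanalytic-variability quality control.
#
# Three screens, all computed on log2(RFU) and blind to the case/control
# contrast of the discovery comparison (they see only control-site, draw
# procedure, and plate covariates, which is what prevents QC from leaking
# outcome information into marker selection):
#
#   1. control-set screen: an analyte whose distribution differs between
#      any pair of control collection sites by a two-sample
#      Kolmogorov-Smirnov distance above threshold (default 0.45) is
#      excluded;
#   2. paired-draw screen: analytes shifted between matched
#      intra-operative and pre-operative draws of the same subjects
#      (Wilcoxon signed-rank p below alpha AND median |log2 ratio| at
#      least a minimum shift) are excluded;
#   3. PCA screen: principal components whose scores track a technical
#      covariate are flagged, along with outlying samples and high-loading
#      analytes on those components; turning flags into exclusions is a
#      separate explicit step.

#' Two-sample Kolmogorov-Smirnov distance
#'
#' Supremum absolute difference between the empirical CDFs of two
#' samples; lies in `[0, 1]`, is symmetric, and is invariant under any
#' strictly monotone transform applied to both samples.
#'
#' @param x,y Non-empty numeric vectors.
#' @return The KS statistic D.
#' @export
ks_distance <- function(x, y) {
  if (!length(x) || !length(y)) stop("ks_distance requires non-empty samples")
  w <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(w) - stats::ecdf(y)(w)))
}

#' Screen analytes for variation between control collection sites
#'
#' For every analyte, computes the KS distance between each pair of
#' eligible control sites on log2 values and excludes the analyte iff the
#' maximum pairwise distance strictly exceeds the threshold.
#'
#' @param m RFU matrix.
#' @param ann Annotation.
#' @param threshold Exclusion threshold on D (default 0.45; strict `>`).
#' @param min_site_n Minimum control samples per site for a site to enter
#'   the comparison (default 5).
#' @return A `qc_fragment` data.frame: `analyte_id`, `max_ks`,
#'   `site_pair`, `excluded`, with attribute `reason = "KS_CONTROL_SETS"`.
#' @export
filter_ks_control_sets <- function(m, ann, threshold = 0.45, min_site_n = 5L) {
  validate_rfu_matrix(m)
  validate_annotation(ann)
  idx <- match(rownames(m), ann$sample_id)
  ctrl <- !is.na(idx) & ann$class_label[idx] == "CONTROL"
  site <- ann$site[idx]
  sites <- names(which(table(site[ctrl]) >= min_site_n))
  if (length(sites) < 2L)
    stop("need >= 2 control sites with >= ", min_site_n, " samples each")
  lv <- log2(m[ctrl & site %in% sites, , drop = FALSE])
  site <- site[ctrl & site %in% sites]
  pairs <- utils::combn(sites, 2L, simplify = FALSE)
  per_pair <- vapply(pairs, function(pr) {
    a <- lv[site == pr[1L], , drop = FALSE]
    b <- lv[site == pr[2L], , drop = FALSE]
    vapply(seq_len(ncol(lv)), function(j) ks_distance(a[, j], b[, j]),
           numeric(1L))
  }, numeric(ncol(lv)))
  per_pair <- matrix(per_pair, ncol = length(pairs))
  which_pair <- max.col(per_pair, ties.method = "first")
  max_ks <- per_pair[cbind(seq_len(nrow(per_pair)), which_pair)]
  frag <- data.frame(
    analyte_id = colnames(m),
    max_ks = max_ks,
    site_pair = vapply(pairs[which_pair], paste, character(1L), collapse = "|"),
    excluded = max_ks > threshold,
    stringsAsFactors = FALSE)
  attr(frag, "reason") <- "KS_CONTROL_SETS"
  attr(frag, "threshold") <- threshold
  class(frag) <- c("qc_fragment", "data.frame")
  frag
}

#' Screen analytes for blood-draw procedure shifts in paired samples
#'
#' Per analyte, forms the paired log2 ratios (intra-operative minus
#' pre-operative, by subject) and excludes the analyte iff the Wilcoxon
#' signed-rank p-value falls below `alpha` AND the absolute median ratio
#' reaches `min_abs_log2_shift`. The conjunction avoids discarding
#' analytes for statistically consistent but trivially small shifts.
#'
#' @param paired_m RFU matrix of the paired draws.
#' @param ann Annotation carrying `subject_id` and `draw_type`.
#' @param alpha Signed-rank significance threshold (default 0.05).
#' @param min_abs_log2_shift Minimum absolute median log2 ratio
#'   (default 0.5).
#' @return A `qc_fragment` data.frame: `analyte_id`, `median_log2_ratio`,
#'   `p_value`, `excluded`, with attribute `reason = "PAIRED_DRAW"`.
#' @export
filter_paired_draws <- function(paired_m, ann, alpha = 0.05,
                                min_abs_log2_shift = 0.5) {
  validate_rfu_matrix(paired_m)
  validate_annotation(ann)
  idx <- match(rownames(paired_m), ann$sample_id)
  if (anyNA(idx)) stop("unannotated paired sample(s)")
  subj <- ann$subject_id[idx]
  draw <- ann$draw_type[idx]
  subjects <- unique(subj[!is.na(subj)])
  have_both <- vapply(subjects, function(s) {
    all(c("PRE_OP", "INTRA_OP") %in% draw[subj == s])
  }, logical(1L))
  subjects <- subjects[have_both]
  if (length(subjects) < 2L)
    stop("need >= 2 subjects with both PRE_OP and INTRA_OP draws")
  pre_idx <- vapply(subjects, function(s)
    which(subj == s & draw == "PRE_OP")[1L], integer(1L))
  intra_idx <- vapply(subjects, function(s)
    which(subj == s & draw == "INTRA_OP")[1L], integer(1L))
  d <- log2(paired_m[intra_idx, , drop = FALSE]) -
    log2(paired_m[pre_idx, , drop = FALSE])
  med <- apply(d, 2L, stats::median)
  pval <- apply(d, 2L, function(v) {
    if (all(v == 0)) return(1)
    suppressWarnings(stats::wilcox.test(v)$p.value)
  })
  frag <- data.frame(
    analyte_id = colnames(paired_m),
    median_log2_ratio = med,
    p_value = pval,
    excluded = pval < alpha & abs(med) >= min_abs_log2_shift,
    stringsAsFactors = FALSE)
  attr(frag, "reason") <- "PAIRED_DRAW"
  attr(frag, "threshold") <- c(alpha = alpha, min_shift = min_abs_log2_shift)
  class(frag) <- c("qc_fragment", "data.frame")
  frag
}

# correlation ratio (eta) between component scores and a categorical
# covariate: sqrt of the between-group share of the total sum of squares.
correlation_ratio <- function(score, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) return(0)
  gm <- tapply(score, group, mean)
  n <- tapply(score, group, length)
  ssb <- sum(n * (gm - mean(score))^2)
  sst <- sum((score - mean(score))^2)
  if (sst == 0) return(0)
  sqrt(ssb / sst)
}

#' PCA screen for preanalytic artifact components, samples, and analytes
#'
#' Standardizes log2 values per analyte, computes principal components of
#' the sample-by-analyte matrix, and flags (i) components explaining at
#' least `var_min` of the variance whose scores correlate with a
#' technical covariate (correlation ratio above `r_threshold`), (ii)
#' samples whose scores on a flagged component sit more than `score_mads`
#' robust MADs from the median, and (iii) analytes in the top decile of
#' absolute loading on a flagged component. The screen only flags;
#' exclusions are assembled explicitly by [qc_report()].
#'
#' The components are derived from the control samples only and all
#' clinical samples are then projected onto them. In surveillance
#' designs the collection covariates (site, draw procedure) are
#' confounded with case status, so a PCA over all samples mixes the
#' disease axis into every batch component and a screen against it
#' would discard genuine disease markers; restricting the decomposition
#' to the control sets is the in-study analogue of identifying
#' preanalytic-variability components from dedicated control
#' experiments. Analyte flags additionally require the loading to sit
#' more than `loading_mads` robust MADs from the component's median
#' absolute loading, so noise-level loadings inside the top decile are
#' not flagged.
#'
#' @param m RFU matrix (calibrator/buffer wells are ignored).
#' @param ann Annotation supplying the technical covariates.
#' @param covariates Annotation columns treated as technical covariates
#'   (default site, draw type, plate).
#' @param r_threshold Correlation-ratio threshold for flagging a
#'   component (default 0.5).
#' @param score_mads Robust-MAD multiple for flagging samples (default 3).
#' @param loading_mads Robust-MAD multiple for the analyte-loading gate
#'   (default 3).
#' @param var_min Minimum variance share for a component to be screened
#'   (default 0.01).
#' @return A `pca_screen` list: `summary` (per-component variance share
#'   and covariate correlations), `flagged_components`,
#'   `flagged_samples`, `flagged_analytes`, `scores`.
#' @export
pca_artifact_screen <- function(m, ann,
                                covariates = c("site", "draw_type", "plate_id"),
                                r_threshold = 0.5, score_mads = 3,
                                loading_mads = 3, var_min = 0.01) {
  validate_rfu_matrix(m)
  validate_annotation(ann)
  idx <- match(rownames(m), ann$sample_id)
  keep <- !is.na(idx) & ann$class_label[idx] %in% c("CASE", "CONTROL")
  m <- m[keep, , drop = FALSE]
  ann_s <- ann[match(rownames(m), ann$sample_id), , drop = FALSE]
  if (nrow(m) < 10L) stop("PCA screen requires >= 10 clinical samples")

  in_ctrl <- ann_s$class_label == "CONTROL"
  if (sum(in_ctrl) < 10L) in_ctrl <- rep(TRUE, nrow(ann_s))
  lv <- log2(m)
  ctr <- colMeans(lv[in_ctrl, , drop = FALSE])
  sds <- apply(lv[in_ctrl, , drop = FALSE], 2L, stats::sd)
  if (all(sds == 0)) stop("degenerate matrix: all analytes constant")
  usable <- sds > 0
  z_ctrl <- scale(lv[in_ctrl, usable, drop = FALSE],
                  center = ctr[usable], scale = sds[usable])
  pc <- stats::prcomp(z_ctrl, center = FALSE, scale. = FALSE)
  varexp <- pc$sdev^2 / sum(pc$sdev^2)
  screened <- which(varexp >= var_min)

  # project every clinical sample onto the control-derived components
  z_all <- scale(lv[, usable, drop = FALSE],
                 center = ctr[usable], scale = sds[usable])
  scores_all <- z_all %*% pc$rotation

  eta <- sapply(covariates, function(cv) {
    g <- ann_s[[cv]][in_ctrl]
    g[is.na(g)] <- "(missing)"
    vapply(screened, function(k) correlation_ratio(pc$x[, k], g),
           numeric(1L))
  })
  eta <- matrix(eta, nrow = length(screened),
                dimnames = list(paste0("PC", screened), covariates))
  max_eta <- if (length(screened)) apply(eta, 1L, max) else numeric(0)
  flagged_comp <- screened[max_eta > r_threshold]

  flagged_samples <- data.frame(sample_id = character(0),
                                component = character(0),
                                score = numeric(0))
  flagged_analytes <- data.frame(analyte_id = character(0),
                                 component = character(0),
                                 loading = numeric(0))
  for (k in flagged_comp) {
    sc <- scores_all[, k]
    md <- stats::median(sc); s <- stats::mad(sc)
    out <- if (s > 0) abs(sc - md) > score_mads * s else rep(FALSE, length(sc))
    if (any(out))
      flagged_samples <- rbind(flagged_samples, data.frame(
        sample_id = rownames(m)[out], component = paste0("PC", k),
        score = sc[out]))
    ld <- abs(pc$rotation[, k])
    gate <- if (stats::mad(ld) > 0)
      ld > stats::median(ld) + loading_mads * stats::mad(ld)
    else ld > 0
    top <- ld >= stats::quantile(ld, 0.9) & gate
    if (any(top))
      flagged_analytes <- rbind(flagged_analytes, data.frame(
        analyte_id = colnames(z_ctrl)[top], component = paste0("PC", k),
        loading = pc$rotation[top, k]))
  }
  res <- list(
    summary = data.frame(component = paste0("PC", screened),
                         var_explained = varexp[screened],
                         max_covariate_eta = if (length(screened)) max_eta
                                             else numeric(0)),
    covariate_eta = eta,
    flagged_components = if (length(flagged_comp))
      paste0("PC", flagged_comp) else character(0),
    flagged_samples = unique(flagged_samples),
    flagged_analytes = unique(flagged_analytes),
    scores = scores_all[, screened, drop = FALSE])
  class(res) <- "pca_screen"
  res
}

#' Assemble a QC report from filter fragments and an optional PCA screen
#'
#' Every exclusion carries its reason (`KS_CONTROL_SETS`, `PAIRED_DRAW`,
#' or `PCA_ARTIFACT`) and the triggering statistic. Turning PCA flags
#' into exclusions is the explicit decision made here, via
#' `include_pca_samples` / `include_pca_analytes`.
#'
#' @param ks Optional fragment from [filter_ks_control_sets()].
#' @param paired Optional fragment from [filter_paired_draws()].
#' @param pca Optional [pca_artifact_screen()] result.
#' @param include_pca_samples,include_pca_analytes Whether PCA flags
#'   become exclusions (defaults `TRUE`).
#' @return A `qc_report`: list with `excluded_analytes`,
#'   `excluded_samples` (id, reason, statistic), plus the underlying
#'   `ks_table`, `paired_table`, and `pca_summary`.
#' @export
qc_report <- function(ks = NULL, paired = NULL, pca = NULL,
                      include_pca_samples = TRUE,
                      include_pca_analytes = TRUE) {
  ex_a <- data.frame(id = character(0), reason = character(0),
                     statistic = numeric(0))
  ex_s <- ex_a
  if (!is.null(ks) && any(ks$excluded))
    ex_a <- rbind(ex_a, data.frame(id = ks$analyte_id[ks$excluded],
                                   reason = "KS_CONTROL_SETS",
                                   statistic = ks$max_ks[ks$excluded]))
  if (!is.null(paired) && any(paired$excluded))
    ex_a <- rbind(ex_a, data.frame(
      id = paired$analyte_id[paired$excluded],
      reason = "PAIRED_DRAW",
      statistic = paired$median_log2_ratio[paired$excluded]))
  if (!is.null(pca)) {
    if (include_pca_analytes && nrow(pca$flagged_analytes))
      ex_a <- rbind(ex_a, data.frame(
        id = pca$flagged_analytes$analyte_id,
        reason = "PCA_ARTIFACT",
        statistic = pca$flagged_analytes$loading))
    if (include_pca_samples && nrow(pca$flagged_samples))
      ex_s <- rbind(ex_s, data.frame(
        id = pca$flagged_samples$sample_id,
        reason = "PCA_ARTIFACT",
        statistic = pca$flagged_samples$score))
  }
  rep <- list(excluded_analytes = ex_a[!duplicated(ex_a$id), , drop = FALSE],
              excluded_samples = ex_s[!duplicated(ex_s$id), , drop = FALSE],
              ks_table = ks, paired_table = paired,
              pca_summary = if (!is.null(pca)) pca$summary else NULL)
  class(rep) <- "qc_report"
  rep
}

#' Apply a QC report to an RFU matrix
#'
#' Drops excluded analytes (columns) and samples (rows); exclusions that
#' refer to ids absent from the matrix (for example paired-cohort-only
#' analyte calls applied to another matrix) are ignored for rows/columns
#' they cannot touch.
#'
#' @param m RFU matrix.
#' @param report A [qc_report()].
#' @param verbose Log exclusion counts by reason (default `FALSE`).
#' @return The filtered RFU matrix.
#' @export
apply_qc <- function(m, report, verbose = FALSE) {
  validate_rfu_matrix(m)
  stopifnot(inherits(report, "qc_report"))
  drop_a <- intersect(colnames(m), report$excluded_analytes$id)
  drop_s <- intersect(rownames(m), report$excluded_samples$id)
  if (verbose) {
    by_reason <- table(report$excluded_analytes$reason)
    message("QC: dropping ", length(drop_a), " analytes (",
            paste(names(by_reason), by_reason, sep = "=", collapse = ", "),
            ") and ", length(drop_s), " samples")
  }
  m[!(rownames(m) %in% drop_s), !(colnames(m) %in% drop_a), drop = FALSE]
}

#' Write a QC report's exclusions to long-format TSV
#'
#' Columns: `id`, `kind` (analyte/sample), `reason`, `statistic`.
#'
#' @param report A [qc_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  df <- rbind(
    if (nrow(report$excluded_analytes))
      cbind(report$excluded_analytes, kind = "analyte"),
    if (nrow(report$excluded_samples))
      cbind(report$excluded_samples, kind = "sample"))
  if (is.null(df))
    df <- data.frame(id = character(0), reason = character(0),
                     statistic = numeric(0), kind = character(0))
  utils::write.table(df[, c("id", "kind", "reason", "statistic")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
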