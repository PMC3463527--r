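# End-to-end orchestration: simulate -> calibrate -> normalize -> QC ->
# split -> discover -> train -> predict -> evaluate, with provenance and
# a blinding audit. The discovery stages (univariate screen, candidate
# selection, Gini ranking, panel scan, model training) receive only
# training-split samples; the run records which ids each stage touched
# and aborts if a held-out id ever reaches discovery.

#' Build a validated pipeline configuration
#'
#' Collects every tunable of the pipeline with defaults describing the
#' reference study design: a discovery cohort of 79 cases and 110
#' controls (40 + 40 clean plus one 30-sample control site carrying a
#' protein-degradation artifact, which QC is expected to remove), twelve
#' paired pre-op/intra-op control subjects, a blinded validation cohort
#' of 38 cases / 62 controls sharing the same analyte structure, a 75/25
#' training/verification split, Benjamini-Hochberg candidate selection
#' at q < 0.01, a 13-analyte panel, and a Youden-maximal out-of-bag
#' decision threshold. Unknown keys are rejected.
#'
#' @param seed Master seed; every stage derives a named substream.
#' @param n_analytes Analyte count (default 1045).
#' @param training_fraction Training share of the discovery cohort.
#' @param ks_threshold,alpha,min_abs_log2_shift,pca_r,pca_mads QC
#'   tunables (see the qc functions).
#' @param q_threshold,candidate_test Candidate-selection rule.
#' @param ntree Trees for every forest (default 1000).
#' @param scan_sizes Panel-size grid.
#' @param panel_size Hard panel-size override (default 13).
#' @param threshold_rule,fixed_threshold Decision-threshold rule.
#' @param prevalence Screening prevalence (default 0.014).
#' @param n_validation_cases,n_validation_controls Validation cohort size.
#' @param discovery_ids Optional explicit discovery-stage sample ids
#'   (normally derived from the split; overriding with held-out ids
#'   makes the run fail its blinding audit).
#' @param cohort_overrides Named list of [cohort_spec()] arguments
#'   applied to the generated cohorts (e.g. a smaller `n_analytes` grid
#'   for quick runs).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            n_analytes = 1045L,
                            training_fraction = 0.75,
                            ks_threshold = 0.45,
                            alpha = 0.05,
                            min_abs_log2_shift = 0.5,
                            pca_r = 0.5,
                            pca_mads = 3,
                            q_threshold = 0.01,
                            candidate_test = "t",
                            ntree = 1000L,
                            scan_sizes = c(1, 2, 3, 5, 8, 13, 21, 34, 51, 64),
                            panel_size = 13L,
                            threshold_rule = "youden",
                            fixed_threshold = NULL,
                            prevalence = 0.014,
                            n_validation_cases = 38L,
                            n_validation_controls = 62L,
                            discovery_ids = NULL,
                            cohort_overrides = list()) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

check_config <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    known <- names(formals(pipeline_config))
    unknown <- setdiff(names(config), known)
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    config <- do.call(pipeline_config, config)
  }
  config
}

#' Run the full surveillance-panel pipeline on a synthetic study
#'
#' Executes the stages in study-flowchart order on synthetic cohorts
#' generated from the configuration's seed: discovery and validation
#' cohorts sharing one analyte structure, plus a paired-draw QC cohort.
#' Verification and validation samples are scored by a model fixed (tree
#' ensemble, panel, and threshold) before their labels are consulted;
#' the provenance record proves it via the per-stage id audit, and any
#' discovery-stage access to a held-out id aborts the run. Identical
#' configurations yield identical outputs.
#'
#' @param config A [pipeline_config()] (or plain list of its arguments).
#' @return An `mm_pipeline_run`: list with `qc`, `split`, `univariate`,
#'   `candidates`, `ranking`, `scan`, `model`, `scores` (per cohort),
#'   `evaluation` (per-cohort and pooled metrics, ROC, stage table,
#'   screening estimates), `truth`, and `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  config <- check_config(config)
  seed <- config$seed
  audit <- list()
  t0 <- Sys.time()

  ## -- simulate ------------------------------------------------------
  disc_args <- utils::modifyList(list(
    n_cases = 79L, n_controls = 110L,
    control_sites = c("SYNTH-KAR", "SYNTH-LIB", "SYNTH-SIN"),
    controls_per_site = c("SYNTH-KAR" = 40L, "SYNTH-LIB" = 40L,
                          "SYNTH-SIN" = 30L),
    degraded_fraction = 1,
    n_analytes = config$n_analytes,
    seed = substream_seed(seed, "discovery"),
    structure_seed = substream_seed(seed, "structure")),
    config$cohort_overrides)
  disc_spec <- do.call(cohort_spec, disc_args)
  discovery <- generate_cohort(disc_spec)
  paired <- generate_paired_draws(disc_spec)

  val_args <- utils::modifyList(disc_args, list(
    n_cases = config$n_validation_cases,
    n_controls = config$n_validation_controls,
    controls_per_site = NULL,
    control_sites = c("SYNTH-KAR", "SYNTH-LIB"),
    degraded_fraction = 0,
    assay_version = "V2", id_prefix = "V",
    seed = substream_seed(seed, "validation")))
  val_spec <- do.call(cohort_spec, val_args)
  validation <- generate_cohort(val_spec)

  ## -- calibrate, then median-normalize ------------------------------
  preprocess <- function(cohort) {
    cal <- calibrate_plates(cohort$matrix, cohort$annotation)
    norm <- median_normalize(cal$calibrated)
    norm$normalized
  }
  m_disc <- preprocess(discovery)
  m_val <- preprocess(validation)

  ## -- preanalytic QC -------------------------------------------------
  ks_frag <- filter_ks_control_sets(m_disc, discovery$annotation,
                                    threshold = config$ks_threshold)
  paired_frag <- filter_paired_draws(paired$matrix, paired$annotation,
                                     alpha = config$alpha,
                                     min_abs_log2_shift = config$min_abs_log2_shift)
  pca <- pca_artifact_screen(m_disc, discovery$annotation,
                             r_threshold = config$pca_r,
                             score_mads = config$pca_mads)
  qc <- qc_report(ks = ks_frag, paired = paired_frag, pca = pca)
  m_qc <- apply_qc(m_disc, qc)
  # analyte exclusions propagate to the validation matrix; its clinical
  # samples are untouched (calibrator wells served preprocessing only)
  val_clin <- validation$annotation$sample_id[
    validation$annotation$class_label %in% c("CASE", "CONTROL")]
  m_val_qc <- m_val[intersect(rownames(m_val), val_clin),
                    intersect(colnames(m_val), colnames(m_qc)),
                    drop = FALSE]

  ## -- split ----------------------------------------------------------
  split <- join_and_split(m_qc, discovery$annotation,
                          training_fraction = config$training_fraction,
                          seed = substream_seed(seed, "split"))
  split$validation_ids <- sort(rownames(m_val_qc))
  held_out <- c(split$verification_ids, split$validation_ids)

  discovery_ids <- config$discovery_ids %||% split$training_ids
  violation <- intersect(discovery_ids, held_out)
  if (length(violation))
    stop("blinding violation: discovery stage given held-out sample id(s): ",
         paste(utils::head(violation, 5L), collapse = ", "))
  audit$discovery_ids <- discovery_ids

  m_train <- m_qc[discovery_ids, , drop = FALSE]
  ann_all <- rbind(discovery$annotation, validation$annotation)

  ## -- discover -------------------------------------------------------
  uni <- univariate_screen(m_train, ann_all)
  cand <- select_candidates(uni, q_threshold = config$q_threshold,
                            test = config$candidate_test)
  ranking <- gini_rank(m_train, ann_all, cand, ntree = config$ntree,
                       seed = substream_seed(seed, "gini"))
  scan <- panel_size_scan(m_train, ann_all, ranking,
                          sizes = config$scan_sizes, ntree = config$ntree,
                          seed = substream_seed(seed, "scan"),
                          force_k = config$panel_size)
  panel <- attr(scan, "panel")

  ## -- train ----------------------------------------------------------
  model <- train_panel_model(m_train, ann_all, panel, ntree = config$ntree,
                             threshold_rule = config$threshold_rule,
                             fixed_threshold = config$fixed_threshold,
                             seed = substream_seed(seed, "forest"))
  model_hash <- content_hash(list(model$panel, model$threshold,
                                  model$training_hash))

  ## -- predict (blinded) ----------------------------------------------
  # training row reported from out-of-bag scores, never resubstitution
  oob_scores <- data.frame(sample_id = names(model$oob_scores),
                           score = unname(model$oob_scores),
                           label = ifelse(model$oob_scores >= model$threshold,
                                          "CASE", "CONTROL"),
                           stringsAsFactors = FALSE)
  class(oob_scores) <- c("score_set", "data.frame")
  sc_verif <- predict(model, m_qc[split$verification_ids, , drop = FALSE])
  sc_valid <- predict(model, m_val_qc)
  audit$verification_ids <- split$verification_ids
  audit$validation_ids <- split$validation_ids

  ## -- evaluate --------------------------------------------------------
  scores <- list(training = oob_scores, verification = sc_verif,
                 validation = sc_valid)
  counts <- lapply(names(scores), function(nm) {
    confusion_from_scores(scores[[nm]], ann_all, cohort = nm)
  })
  names(counts) <- names(scores)
  counts$combined <- pool_cohorts(counts)
  metrics <- lapply(counts, confusion_metrics)
  is_case <- function(sc) ann_all$class_label[
    match(sc$sample_id, ann_all$sample_id)] == "CASE"
  rocs <- lapply(scores, function(sc) roc_auc(sc$score, is_case(sc)))
  stage_tables <- lapply(scores, function(sc) stage_sensitivity(sc, ann_all))
  stage_combined <- pool_stage_tables(stage_tables)
  comb <- metrics$combined
  screening <- screening_estimates(
    comb$estimate[comb$metric == "sensitivity"] / 100,
    comb$estimate[comb$metric == "specificity"] / 100,
    prevalence = config$prevalence)

  provenance <- list(
    config = config,
    seed = seed,
    started = t0, finished = Sys.time(),
    model_hash = model_hash,
    stage_hashes = list(
      qc = content_hash(qc$excluded_analytes),
      split = content_hash(split[c("training_ids", "verification_ids",
                                   "validation_ids")]),
      panel = content_hash(panel),
      scores = content_hash(lapply(scores, function(s) s[c("sample_id", "score")]))),
    id_audit = audit,
    blinding_ok = length(intersect(audit$discovery_ids, held_out)) == 0L)

  run <- list(qc = qc, split = split, univariate = uni, candidates = cand,
              ranking = ranking, scan = scan, model = model,
              scores = scores, counts = counts,
              evaluation = list(metrics = metrics, roc = rocs,
                                stage = stage_tables,
                                stage_combined = stage_combined,
                                screening = screening),
              truth = list(discovery = discovery$truth,
                           validation = validation$truth),
              provenance = provenance)
  class(run) <- "mm_pipeline_run"
  run
}

#' @export
print.mm_pipeline_run <- function(x, ...) {
  cat("mm surveillance pipeline run (seed", x$provenance$seed, ")\n")
  cat("  analytes after QC:",
      sum(!x$univariate$analyte_id %in% x$qc$excluded_analytes$id), "\n")
  cat("  candidates:", length(x$candidates$analyte_ids),
      "| panel size:", length(x$model$panel), "\n")
  for (nm in names(x$evaluation$metrics)) {
    mtr <- x$evaluation$metrics[[nm]]
    cat(sprintf("  %-12s sens %.1f  spec %.1f  acc %.1f\n", nm,
                mtr$estimate[1L], mtr$estimate[2L], mtr$estimate[3L]))
  }
  cat("  blinding audit:",
      if (x$provenance$blinding_ok) "clean" else "VIOLATION", "\n")
  invisible(x)
}
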