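# Synthetic cohort generator.
#
# Emulates the statistical structure of a multi-center aptamer-proteomic
# case-control serum study: ~1045 log-normal analytes; a small set of
# truly differential markers with signed case effects that scale with
# pathologic stage; additional weaker spiked markers; per-site batch
# offsets on analyte subsets; per-plate multiplicative biases with eight
# calibrator wells per plate; a degraded control sub-cohort (protein
# degradation artifact); analytes shifted by the blood-draw procedure
# (intra-operative vs pre-operative); and paired draws from control
# subjects for the paired-draw QC filter.
#
# All structure (which analytes are markers, artifacts, degradation-
# susceptible, site-affected; baselines; effect sizes) derives from
# `structure_seed`, and all sample-level noise from `seed`, each through
# named substreams. Two cohorts sharing a structure_seed therefore share
# the same underlying biology, which is how a blinded validation cohort
# is generated for a model trained on a discovery cohort.

#' Specify a synthetic serum proteomics cohort
#'
#' Defaults describe the study conditions the pipeline is designed for:
#' 1045 analytes of which 13 strong markers (9 up, 4 down, 1.0 log2-unit
#' case effect) and 51 weaker markers (0.5 log2 units) are spiked, for 64
#' differential candidates in total; stage multipliers 0.5/0.75/1.0/1.25
#' for stages I-IV; log-normal baselines with residual log2 SD 0.5; eight
#' calibrator wells per plate; and twelve paired pre-op/intra-op control
#' subjects.
#'
#' @param n_cases,n_controls Clinical sample counts.
#' @param n_analytes Number of protein analytes (default 1045).
#' @param n_true_markers Strong spiked markers (default 13).
#' @param n_weak_markers Additional weaker spiked markers (default 51).
#' @param true_effect_log2,weak_effect_log2 Absolute case effect sizes in
#'   log2-RFU units for strong/weak markers (defaults 1.0 and 0.5).
#' @param n_down_markers How many of the strong markers are
#'   down-regulated in cases (default 4; the rest are up).
#' @param stage_gradient Named multipliers applied to the case effect per
#'   pathologic stage; emulates signal growth with disease burden.
#' @param stage_probs Named stage frequencies for cases.
#' @param case_sites,control_sites Collection-site labels for cases and
#'   controls (`SYNTH-` prefixed). The default places the controls in
#'   two sets of 30: the 0.45 KS control-set screen is calibrated for
#'   control sets of at least ~30 samples, where its null exclusion
#'   rate is negligible.
#' @param cases_per_site,controls_per_site Optional named integer
#'   allocations; default splits evenly with remainders to earlier sites.
#' @param site_affected_frac Fraction of analytes per site carrying a
#'   site batch offset (default 0.03).
#' @param site_shift_log2 Absolute magnitude of site offsets (default 1.0).
#' @param degraded_site Control site whose samples may carry the
#'   degradation artifact.
#' @param degraded_fraction Fraction of that site's samples degraded
#'   (default 0; the pipeline's discovery cohort uses 1).
#' @param degradation_analyte_frac Fraction of analytes susceptible to
#'   degradation (default 0.2).
#' @param degradation_shift_log2 Degradation shift (default -1.5).
#' @param n_artifact_analytes Analytes shifted by the intra-operative
#'   draw procedure (default 30).
#' @param draw_shift_log2 Intra-op shift on artifact analytes (default 1.5).
#' @param case_intra_op_frac Fraction of cases drawn intra-operatively
#'   (default 0.6; controls are clinic draws), reproducing the
#'   case/draw-procedure confounding that motivates the paired filter.
#' @param n_paired_subjects Control subjects with both draw types
#'   (default 12).
#' @param n_plates Number of assay plates; default packs samples plus
#'   calibrators into 96-well plates.
#' @param plate_bias_sd SD of per-plate log2 biases (default 0.2).
#' @param plate_log2_bias Optional explicit per-plate log2 biases
#'   (recycled/truncated to the plate count); overrides `plate_bias_sd`.
#' @param calibrators_per_plate Calibrator wells per plate (default 8).
#' @param calibrator_noise_sd Technical SD of calibrator wells (default 0.1).
#' @param baseline_log2_mean,baseline_log2_sd Distribution of per-analyte
#'   log2 baselines (defaults 10 and 1.5).
#' @param noise_sd Residual per-measurement log2 SD (default 0.5).
#' @param subject_sd Between-subject log2 SD shared by a subject's paired
#'   draws (default 0.3).
#' @param assay_version Assay version label stamped on the annotation.
#' @param id_prefix Prefix for generated sample/calibrator ids, so
#'   matrices from several cohorts can coexist in one analysis.
#' @param seed Master seed for sample-level randomness.
#' @param structure_seed Seed for cohort structure; defaults to `seed`.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_cases = 60, n_controls = 60,
                        n_analytes = 1045,
                        n_true_markers = 13, n_weak_markers = 51,
                        true_effect_log2 = 1.0, weak_effect_log2 = 0.5,
                        n_down_markers = 4,
                        stage_gradient = c(I = 0.5, II = 0.75, III = 1.0,
                                           IV = 1.25, UNKNOWN = 1.0),
                        stage_probs = c(I = 0.11, II = 0.23, III = 0.42,
                                        IV = 0.22, UNKNOWN = 0.02),
                        case_sites = c("SYNTH-NYU", "SYNTH-KAR"),
                        control_sites = c("SYNTH-KAR", "SYNTH-LIB"),
                        cases_per_site = NULL, controls_per_site = NULL,
                        site_affected_frac = 0.03, site_shift_log2 = 1.0,
                        degraded_site = "SYNTH-SIN", degraded_fraction = 0,
                        degradation_analyte_frac = 0.2,
                        degradation_shift_log2 = -1.5,
                        n_artifact_analytes = 30, draw_shift_log2 = 1.5,
                        case_intra_op_frac = 0.6,
                        n_paired_subjects = 12,
                        n_plates = NULL, plate_bias_sd = 0.2,
                        plate_log2_bias = NULL,
                        calibrators_per_plate = 8, calibrator_noise_sd = 0.1,
                        baseline_log2_mean = 10, baseline_log2_sd = 1.5,
                        noise_sd = 0.5, subject_sd = 0.3,
                        assay_version = "V1", id_prefix = "",
                        seed = 1L, structure_seed = seed) {
  spec <- as.list(environment())
  counts <- c(n_cases, n_controls, n_analytes, n_true_markers,
              n_weak_markers, n_artifact_analytes, n_paired_subjects,
              calibrators_per_plate)
  if (any(counts < 0)) stop("cohort_spec counts must be non-negative")
  if (n_true_markers + n_weak_markers > n_analytes)
    stop("n_true_markers + n_weak_markers must not exceed n_analytes")
  if (n_down_markers > n_true_markers)
    stop("n_down_markers must not exceed n_true_markers")
  if (degraded_fraction < 0 || degraded_fraction > 1)
    stop("degraded_fraction must lie in [0, 1]")
  if (!degraded_site %in% control_sites && degraded_fraction > 0)
    stop("degraded_site must be one of control_sites")
  stopifnot(all(names(stage_gradient) %in% STAGES),
            all(names(stage_probs) %in% STAGES))
  class(spec) <- "cohort_spec"
  spec
}

# Even allocation of n items over k bins, remainders to earlier bins.
even_alloc <- function(n, bins) {
  k <- length(bins)
  base <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  stats::setNames(base, bins)
}

# Cohort structure: everything tied to the analyte panel rather than to
# individual samples. Deterministic in structure_seed alone.
cohort_structure <- function(spec) {
  p <- spec$n_analytes
  analyte_ids <- sprintf("A%04d", seq_len(p))
  with_seed(substream_seed(spec$structure_seed, "structure"), {
    baseline <- stats::rnorm(p, spec$baseline_log2_mean, spec$baseline_log2_sd)
    names(baseline) <- analyte_ids

    n_spiked <- spec$n_true_markers + spec$n_weak_markers
    spiked <- if (n_spiked > 0) sample(analyte_ids, n_spiked) else character()
    true_ids <- utils::head(spiked, spec$n_true_markers)
    weak_ids <- utils::tail(spiked, spec$n_weak_markers)

    effects <- numeric(0)
    if (length(true_ids)) {
      sgn <- rep(1, length(true_ids))
      if (spec$n_down_markers > 0)
        sgn[sample(seq_along(true_ids), spec$n_down_markers)] <- -1
      effects <- c(effects, stats::setNames(sgn * spec$true_effect_log2, true_ids))
    }
    if (length(weak_ids)) {
      sgn <- sample(c(-1, 1), length(weak_ids), replace = TRUE)
      effects <- c(effects, stats::setNames(sgn * spec$weak_effect_log2, weak_ids))
    }

    pool <- setdiff(analyte_ids, spiked)
    artifact_ids <- if (spec$n_artifact_analytes > 0)
      sample(pool, min(spec$n_artifact_analytes, length(pool))) else character()
    pool <- setdiff(pool, artifact_ids)

    n_degr <- round(spec$degradation_analyte_frac * p)
    degradation_ids <- if (n_degr > 0) sample(pool, min(n_degr, length(pool)))
      else character()

    # site offsets: each site perturbs its own random non-marker analyte
    # subset by +/- site_shift_log2 (degradation ids stay eligible; the
    # two artifacts are distinct mechanisms and may co-occur)
    sites <- unique(c(spec$case_sites, spec$control_sites))
    site_pool <- setdiff(analyte_ids, spiked)
    n_site <- round(spec$site_affected_frac * p)
    site_offsets <- matrix(0, nrow = p, ncol = length(sites),
                           dimnames = list(analyte_ids, sites))
    for (s in sites) {
      if (n_site > 0) {
        aff <- sample(site_pool, min(n_site, length(site_pool)))
        site_offsets[aff, s] <- sample(c(-1, 1), length(aff), replace = TRUE) *
          spec$site_shift_log2
      }
    }

    draw_shift <- stats::setNames(rep(0, p), analyte_ids)
    draw_shift[artifact_ids] <- spec$draw_shift_log2
    degr_shift <- stats::setNames(rep(0, p), analyte_ids)
    degr_shift[degradation_ids] <- spec$degradation_shift_log2

    list(analyte_ids = analyte_ids, baseline = baseline,
         true_marker_ids = sort(true_ids), weak_marker_ids = sort(weak_ids),
         effects = effects, artifact_analyte_ids = sort(artifact_ids),
         degradation_analyte_ids = sort(degradation_ids),
         site_offsets = site_offsets, draw_shift = draw_shift,
         degradation_shift = degr_shift)
  })
}

#' Generate a synthetic case-control RFU cohort
#'
#' Draws a complete cohort from a [cohort_spec()]: for analyte `a` in
#' sample `s`, `log2 RFU = baseline_a + site offset + case effect_a *
#' stage multiplier (cases, marker analytes) + draw shift_a (intra-op
#' draws, artifact analytes) + degradation shift_a (degraded samples,
#' susceptible analytes) + plate log2 bias + N(0, noise_sd)`, then
#' exponentiated. Calibrator wells are generated at the fixed per-analyte
#' baseline plus plate bias and technical noise. Fully reproducible from
#' the spec's seeds.
#'
#' @param spec A [cohort_spec()].
#' @return List with `matrix` (RFU, samples + calibrators in rows),
#'   `annotation`, and `truth` (ground-truth record: marker/artifact/
#'   degradation analyte ids, degraded sample ids, per-plate log2 biases,
#'   per-marker signed effects).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  st <- cohort_structure(spec)
  p <- spec$n_analytes

  with_seed(substream_seed(spec$seed, "samples"), {
    n <- spec$n_cases + spec$n_controls
    sample_ids <- c(sprintf("%sMM%03d", spec$id_prefix, seq_len(spec$n_cases)),
                    sprintf("%sAC%03d", spec$id_prefix, seq_len(spec$n_controls)))
    is_case <- c(rep(TRUE, spec$n_cases), rep(FALSE, spec$n_controls))

    alloc_cases <- spec$cases_per_site %||% even_alloc(spec$n_cases, spec$case_sites)
    alloc_ctrls <- spec$controls_per_site %||%
      even_alloc(spec$n_controls, spec$control_sites)
    if (sum(alloc_cases) != spec$n_cases || sum(alloc_ctrls) != spec$n_controls)
      stop("per-site allocations must sum to the cohort sizes")
    site <- c(sample(rep(names(alloc_cases), alloc_cases)),
              sample(rep(names(alloc_ctrls), alloc_ctrls)))

    stage <- rep(NA_character_, n)
    stage[is_case] <- sample(names(spec$stage_probs), spec$n_cases,
                             replace = TRUE, prob = spec$stage_probs)
    histology <- rep(NA_character_, n)
    histology[is_case] <- sample(c("EPITHELIAL", "BIPHASIC", "SARCOMATOID",
                                   "UNKNOWN"),
                                 spec$n_cases, replace = TRUE,
                                 prob = c(0.55, 0.22, 0.07, 0.16))
    draw <- ifelse(is_case,
                   ifelse(stats::runif(n) < spec$case_intra_op_frac,
                          "INTRA_OP", "PRE_OP"),
                   "CLINIC")

    degraded <- rep(FALSE, n)
    at_degr_site <- which(!is_case & site == spec$degraded_site)
    n_degr <- round(spec$degraded_fraction * length(at_degr_site))
    if (n_degr > 0)
      degraded[sample(at_degr_site, n_degr)] <- TRUE

    # plate layout: samples + calibrators packed into 96-well plates
    wells_per_plate <- 96L - spec$calibrators_per_plate
    n_plates <- spec$n_plates %||% max(1L, ceiling(n / wells_per_plate))
    plate <- sample(rep(sprintf("P%02d", seq_len(n_plates)),
                        length.out = n))
    plate_levels <- sprintf("P%02d", seq_len(n_plates))
    plate_bias <- if (!is.null(spec$plate_log2_bias))
      rep_len(spec$plate_log2_bias, n_plates)
    else stats::rnorm(n_plates, 0, spec$plate_bias_sd)
    names(plate_bias) <- plate_levels

    # clinical sample log2 intensities
    stage_mult <- rep(0, n)
    stage_mult[is_case] <- spec$stage_gradient[stage[is_case]]
    effect_row <- stats::setNames(rep(0, p), st$analyte_ids)
    effect_row[names(st$effects)] <- st$effects

    log2v <- matrix(rep(st$baseline, each = n), nrow = n,
                    dimnames = list(sample_ids, st$analyte_ids))
    log2v <- log2v + t(st$site_offsets[, site, drop = FALSE])
    log2v <- log2v + outer(stage_mult, effect_row)
    log2v <- log2v + outer(as.numeric(draw == "INTRA_OP"), st$draw_shift)
    log2v <- log2v + outer(as.numeric(degraded), st$degradation_shift)
    log2v <- log2v + plate_bias[plate]
    log2v <- log2v + matrix(stats::rnorm(n * p, 0, spec$noise_sd), nrow = n)

    # calibrator wells at fixed known log-means plus plate bias
    n_cal <- n_plates * spec$calibrators_per_plate
    cal_ids <- character(0); cal_plate <- character(0)
    cal_log2 <- NULL
    if (n_cal > 0) {
      cal_plate <- rep(plate_levels, each = spec$calibrators_per_plate)
      cal_ids <- sprintf("%sCAL_%s_%02d", spec$id_prefix, cal_plate,
                         rep(seq_len(spec$calibrators_per_plate), n_plates))
      cal_log2 <- matrix(rep(st$baseline, each = n_cal), nrow = n_cal,
                         dimnames = list(cal_ids, st$analyte_ids)) +
        plate_bias[cal_plate] +
        matrix(stats::rnorm(n_cal * p, 0, spec$calibrator_noise_sd),
               nrow = n_cal)
    }

    m <- 2 ^ rbind(log2v, cal_log2)
    ann <- data.frame(
      sample_id = c(sample_ids, cal_ids),
      class_label = c(ifelse(is_case, "CASE", "CONTROL"),
                      rep("CALIBRATOR", length(cal_ids))),
      site = c(site, rep("SYNTH-LAB", length(cal_ids))),
      draw_type = c(draw, rep(NA_character_, length(cal_ids))),
      subject_id = c(sample_ids, rep(NA_character_, length(cal_ids))),
      plate_id = c(plate, cal_plate),
      stage = c(stage, rep(NA_character_, length(cal_ids))),
      histology = c(histology, rep(NA_character_, length(cal_ids))),
      assay_version = spec$assay_version,
      stringsAsFactors = FALSE)
    validate_annotation(ann)
    validate_rfu_matrix(m)

    truth <- list(true_marker_ids = st$true_marker_ids,
                  weak_marker_ids = st$weak_marker_ids,
                  artifact_analyte_ids = st$artifact_analyte_ids,
                  degradation_analyte_ids = st$degradation_analyte_ids,
                  degraded_sample_ids = sort(sample_ids[degraded]),
                  site_offsets = st$site_offsets,
                  plate_log2_bias = plate_bias,
                  effects = st$effects)
    list(matrix = m, annotation = ann, truth = truth)
  })
}

#' Generate paired pre-operative/intra-operative control draws
#'
#' Two rows per control subject sharing a `subject_id` and differing only
#' in `draw_type`: artifact analytes are shifted by the spec's draw shift
#' in the intra-operative row, all other analytes differ only by noise
#' around a shared subject level. Feeds the paired-draw QC filter.
#'
#' @param spec A [cohort_spec()] with `n_paired_subjects >= 1`.
#' @return List with `matrix` and `annotation` (2 x n_paired_subjects rows).
#' @export
generate_paired_draws <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_paired_subjects < 1) stop("n_paired_subjects must be >= 1")
  st <- cohort_structure(spec)
  p <- spec$n_analytes
  ns <- spec$n_paired_subjects

  with_seed(substream_seed(spec$seed, "paired"), {
    subjects <- sprintf("PS%02d", seq_len(ns))
    subj_fx <- matrix(stats::rnorm(ns * p, 0, spec$subject_sd), nrow = ns,
                      dimnames = list(subjects, st$analyte_ids))
    base <- matrix(rep(st$baseline, each = ns), nrow = ns) + subj_fx
    draw_noise <- function() matrix(stats::rnorm(ns * p, 0,
                                                 spec$noise_sd / sqrt(2)),
                                    nrow = ns)
    pre <- base + draw_noise()
    intra <- base + matrix(rep(st$draw_shift, each = ns), nrow = ns) +
      draw_noise()
    ids_pre <- paste0(subjects, "_PRE")
    ids_intra <- paste0(subjects, "_INTRA")
    m <- 2 ^ rbind(pre, intra)
    rownames(m) <- c(ids_pre, ids_intra)
    ann <- data.frame(
      sample_id = c(ids_pre, ids_intra),
      class_label = "CONTROL",
      site = "SYNTH-KAR",
      draw_type = rep(c("PRE_OP", "INTRA_OP"), each = ns),
      subject_id = rep(subjects, 2L),
      plate_id = "P01",
      stage = NA_character_,
      histology = NA_character_,
      assay_version = spec$assay_version,
      stringsAsFactors = FALSE)
    validate_annotation(ann)
    validate_rfu_matrix(m)
    list(matrix = m, annotation = ann)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
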