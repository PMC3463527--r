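# Median normalization and calibrator-based inter-plate scaling.
#
# Both corrections are purely multiplicative. Median normalization aligns
# every sample to a common per-analyte reference: the per-sample factor is
# the median over analytes of reference/value, which makes re-applying the
# transform with the same reference an exact identity. Plate calibration
# applies a per-(plate, analyte) factor derived from the calibrator wells
# run on every plate; the reference is the median across plates of the
# per-plate calibrator medians, which likewise makes calibration
# idempotent. The pipeline default order is calibrate first, then
# normalize, so plate bias cannot contaminate the common reference.

#' Median-normalize samples to a common reference
#'
#' Computes per-sample scale factors `f_s = median_a(reference_a /
#' value_sa)` and multiplies each sample row by its factor. After
#' normalization the median over analytes of `reference_a /
#' normalized_sa` is exactly 1 for every sample. The factor uses the
#' median of ratios (not the ratio of medians), making it invariant
#' under per-analyte reweighting.
#'
#' @param m RFU matrix.
#' @param reference Optional per-analyte positive reference values (named
#'   or in column order); default is the per-analyte median across the
#'   samples of `m`.
#' @return A `normalization_result`: list with `normalized` (RFU matrix),
#'   `sample_scale_factors`, and `reference`.
#' @export
median_normalize <- function(m, reference = NULL) {
  validate_rfu_matrix(m)
  if (is.null(reference)) {
    reference <- apply(m, 2L, stats::median)
  } else {
    if (!is.null(names(reference))) {
      missing_ref <- setdiff(colnames(m), names(reference))
      if (length(missing_ref))
        stop("reference missing analyte(s): ",
             paste(utils::head(missing_ref, 5L), collapse = ", "))
      reference <- reference[colnames(m)]
    }
    if (length(reference) != ncol(m))
      stop("reference length must match the number of analytes")
    if (any(!is.finite(reference) | reference <= 0))
      stop("reference values must be strictly positive")
  }
  f <- apply(sweep(1 / m, 2L, reference, `*`), 1L, stats::median)
  out <- m * f
  res <- list(normalized = out,
              sample_scale_factors = f,
              reference = stats::setNames(reference, colnames(m)))
  class(res) <- "normalization_result"
  res
}

#' Calibrate plates with reference calibrator wells
#'
#' For each plate `p` and analyte `a`, the factor `g_pa = reference_a /
#' median(calibrator values of a on plate p)` is applied to every sample
#' on that plate. When no reference is supplied it is the median across
#' plates of the per-plate calibrator medians, so calibrating an
#' already-calibrated matrix returns factors identically 1.
#'
#' @param m RFU matrix including calibrator wells.
#' @param ann Annotation identifying `CALIBRATOR` rows and `plate_id`.
#' @param reference Optional per-analyte calibrator target values.
#' @param expected_calibrators Expected calibrator wells per plate; a
#'   deviation triggers a warning (default 8).
#' @return A `calibration_result`: list with `calibrated` (RFU matrix),
#'   `scale_factors` (plates x analytes), and `calibrator_reference`.
#' @export
calibrate_plates <- function(m, ann, reference = NULL,
                             expected_calibrators = 8L) {
  validate_rfu_matrix(m)
  validate_annotation(ann)
  idx <- match(rownames(m), ann$sample_id)
  if (anyNA(idx))
    stop("unannotated sample(s): ",
         paste(rownames(m)[is.na(idx)], collapse = ", "))
  plate <- ann$plate_id[idx]
  is_cal <- ann$class_label[idx] == "CALIBRATOR"
  plates <- sort(unique(plate))
  no_cal <- plates[!plates %in% unique(plate[is_cal])]
  if (length(no_cal))
    stop("plate(s) without calibrator wells: ", paste(no_cal, collapse = ", "))
  n_cal <- table(plate[is_cal])
  if (any(n_cal != expected_calibrators))
    warning("plate(s) with calibrator count != ", expected_calibrators, ": ",
            paste(names(n_cal)[n_cal != expected_calibrators], collapse = ", "))

  # per-plate, per-analyte calibrator medians
  plate_median <- t(vapply(plates, function(pl) {
    apply(m[is_cal & plate == pl, , drop = FALSE], 2L, stats::median)
  }, numeric(ncol(m))))
  rownames(plate_median) <- plates

  if (is.null(reference)) {
    reference <- apply(plate_median, 2L, stats::median)
  } else {
    if (!is.null(names(reference))) reference <- reference[colnames(m)]
    if (length(reference) != ncol(m) || any(!is.finite(reference) | reference <= 0))
      stop("calibrator reference must give one positive value per analyte")
  }
  g <- sweep(1 / plate_median, 2L, reference, `*`)  # plates x analytes
  out <- m * g[plate, , drop = FALSE]
  res <- list(calibrated = out,
              scale_factors = g,
              calibrator_reference = stats::setNames(reference, colnames(m)))
  class(res) <- "calibration_result"
  res
}
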