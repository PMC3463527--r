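# Core data containers and tabular IO.
#
# An RFU matrix is a plain numeric matrix, samples in rows and protein
# analytes in columns, with unique dimnames and strictly positive entries
# (relative fluorescence units are positive intensities; a zero or missing
# cell is a load-time error, never imputed). Sample annotations are a
# data.frame with one row per sample and a controlled vocabulary per
# column. Matching between the two is exact, case-sensitive string match.

CLASS_LABELS <- c("CASE", "CONTROL", "CALIBRATOR", "BUFFER")
DRAW_TYPES   <- c("PRE_OP", "INTRA_OP", "CLINIC")
STAGES       <- c("I", "II", "III", "IV", "UNKNOWN")
HISTOLOGIES  <- c("EPITHELIAL", "BIPHASIC", "SARCOMATOID", "UNKNOWN")
ASSAY_VERSIONS <- c("V1", "V2")
KNOWN_SITES  <- c("NYU", "KAR", "LIB", "SIN")

ANNOTATION_COLUMNS <- c("sample_id", "class_label", "site", "draw_type",
                        "subject_id", "plate_id", "stage", "histology",
                        "assay_version")

#' Validate an RFU matrix
#'
#' Checks the container invariants: numeric matrix, unique non-empty
#' sample and analyte identifiers, no missing cells, and strictly
#' positive intensities.
#'
#' @param m Numeric matrix, samples in rows, analytes in columns.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_rfu_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("RFU matrix must be a numeric matrix (samples x analytes)")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("RFU matrix must carry sample ids (rownames) and analyte ids (colnames)")
  if (anyDuplicated(rownames(m)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicate analyte ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  bad <- which(is.na(m) | m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf(
      "non-positive or missing RFU value at sample '%s', analyte '%s'",
      rownames(m)[i], colnames(m)[j]))
  }
  invisible(m)
}

#' Read an RFU matrix from tab-separated text
#'
#' Expected layout: header row `sample_id<TAB>analyte ids...`, then one
#' row per sample with plain decimal intensities. Loading is strict:
#' duplicate identifiers, ragged rows, and non-numeric or non-positive
#' cells are hard errors naming the offender. Row and column order is
#' preserved from the file.
#'
#' @param path Path to a TSV file.
#' @return Validated numeric matrix (samples x analytes).
#' @export
read_rfu_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("RFU file must contain a header and at least one sample row: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L)
    stop("RFU header must list at least one analyte: ", path)
  analyte_ids <- header[-1L]
  body <- fields[-1L]
  widths <- lengths(body)
  if (any(widths != length(header))) {
    r <- which(widths != length(header))[1L]
    stop(sprintf("ragged row %d: %d fields, expected %d",
                 r + 1L, widths[r], length(header)))
  }
  sample_ids <- vapply(body, `[[`, character(1L), 1L)
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(analyte_ids),
                 dimnames = list(sample_ids, analyte_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("non-numeric cell at sample '%s', analyte '%s'",
                   sample_ids[i], analyte_ids[j]))
    }
    vals[i, ] <- v
  }
  validate_rfu_matrix(vals)
  vals
}

#' Write an RFU matrix to tab-separated text
#'
#' Canonical format: values printed with 6 significant digits, so
#' write/read round-trips are identity up to that precision and
#' re-writing a freshly read file is byte-identical.
#'
#' @param m Validated RFU matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rfu_matrix <- function(m, path) {
  validate_rfu_matrix(m)
  header <- paste(c("sample_id", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.6g", m[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

valid_site <- function(site) {
  site %in% KNOWN_SITES | startsWith(site, "SYNTH-")
}

#' Validate a sample annotation table
#'
#' Enforces the annotation contract: required columns, controlled
#' vocabularies, and the clinical invariants (cases carry a stage,
#' controls and calibrators do not; calibrators carry no histology).
#' `NA` is legal for `draw_type`, `subject_id`, `stage`, and `histology`
#' where the vocabulary allows it.
#'
#' @param ann data.frame of sample annotations.
#' @return `ann`, invisibly, if valid.
#' @export
validate_annotation <- function(ann) {
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(ann))
  if (length(missing_cols))
    stop("annotation missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample_id in annotation: ",
         paste(unique(ann$sample_id[duplicated(ann$sample_id)]), collapse = ", "))
  check_vocab <- function(x, vocab, col, na_ok = TRUE) {
    bad <- !(x %in% vocab) & !(na_ok & is.na(x))
    if (any(bad))
      stop(sprintf("invalid %s token(s): %s", col,
                   paste(unique(x[bad]), collapse = ", ")))
  }
  check_vocab(ann$class_label, CLASS_LABELS, "class_label", na_ok = FALSE)
  bad_site <- !valid_site(ann$site)
  if (any(bad_site))
    stop("invalid site token(s): ", paste(unique(ann$site[bad_site]), collapse = ", "))
  check_vocab(ann$draw_type, DRAW_TYPES, "draw_type")
  check_vocab(ann$stage, STAGES, "stage")
  check_vocab(ann$histology, HISTOLOGIES, "histology")
  check_vocab(ann$assay_version, ASSAY_VERSIONS, "assay_version", na_ok = FALSE)

  is_case <- ann$class_label == "CASE"
  is_control <- ann$class_label == "CONTROL"
  is_calib <- ann$class_label == "CALIBRATOR"
  if (any(is_case & is.na(ann$stage)))
    stop("CASE rows must carry a stage (UNKNOWN allowed): ",
         paste(ann$sample_id[is_case & is.na(ann$stage)], collapse = ", "))
  if (any(is_control & !is.na(ann$stage)))
    stop("CONTROL rows must carry stage NA: ",
         paste(ann$sample_id[is_control & !is.na(ann$stage)], collapse = ", "))
  if (any(is_calib & (!is.na(ann$stage) | !is.na(ann$histology))))
    stop("CALIBRATOR rows must carry stage and histology NA: ",
         paste(ann$sample_id[is_calib &
                 (!is.na(ann$stage) | !is.na(ann$histology))], collapse = ", "))
  invisible(ann)
}

#' Read a sample annotation table from TSV
#'
#' @param path Path to a TSV with the columns `sample_id, class_label,
#'   site, draw_type, subject_id, plate_id, stage, histology,
#'   assay_version`; the literal token `NA` encodes missing.
#' @return Validated annotation data.frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, colClasses = "character",
                           na.strings = "NA", stringsAsFactors = FALSE)
  validate_annotation(ann)
  ann
}

#' Write a sample annotation table to TSV
#'
#' @param ann Validated annotation data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  validate_annotation(ann)
  utils::write.table(ann[, ANNOTATION_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Stratified training/verification split of a study cohort
#'
#' Joins an RFU matrix with its annotation and splits the clinical
#' samples (calibrator and buffer wells are excluded from every split)
#' into a training set and a held-out verification set, stratified by
#' class label with proportional allocation and largest-remainder
#' rounding. Deterministic given `seed`. Samples listed in
#' `validation_ids` are reserved for a later blinded validation cohort
#' and enter neither set.
#'
#' @param m RFU matrix.
#' @param ann Annotation covering every sample in `m`.
#' @param training_fraction Fraction of eligible samples for training,
#'   in (0, 1). Default 0.75, the conventional 75/25 discovery split.
#' @param seed Integer seed.
#' @param validation_ids Optional sample ids reserved for validation.
#' @return A `study_split`: list with `training_ids`, `verification_ids`,
#'   `validation_ids`, and `seed`.
#' @export
join_and_split <- function(m, ann, training_fraction = 0.75, seed = 1L,
                           validation_ids = character()) {
  validate_rfu_matrix(m)
  validate_annotation(ann)
  if (!(training_fraction > 0 && training_fraction < 1))
    stop("training_fraction must lie in (0, 1)")
  unann <- setdiff(rownames(m), ann$sample_id)
  if (length(unann))
    stop("unannotated sample(s): ", paste(unann, collapse = ", "))
  idx <- match(rownames(m), ann$sample_id)
  lab <- ann$class_label[idx]
  eligible <- rownames(m)[lab %in% c("CASE", "CONTROL") &
                            !(rownames(m) %in% validation_ids)]
  lab <- ann$class_label[match(eligible, ann$sample_id)]
  n_total <- length(eligible)
  if (n_total < 2L) stop("need at least 2 eligible samples to split")
  target <- round(training_fraction * n_total)

  classes <- sort(unique(lab))
  n_class <- vapply(classes, function(cl) sum(lab == cl), integer(1L))
  quota <- training_fraction * n_class
  take <- floor(quota)
  rem <- target - sum(take)
  if (rem > 0) {
    # largest-remainder allocation; ties broken by class name order
    ord <- order(-(quota - take), classes)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
  }
  training <- with_seed(seed, {
    unlist(lapply(seq_along(classes), function(k) {
      ids <- eligible[lab == classes[k]]
      sample(ids, take[k])
    }), use.names = FALSE)
  })
  split <- list(training_ids = sort(training),
                verification_ids = sort(setdiff(eligible, training)),
                validation_ids = sort(intersect(rownames(m), validation_ids)),
                seed = as.integer(seed))
  class(split) <- "study_split"
  split
}

#' Write a split manifest to TSV
#'
#' Long format: columns `sample_id`, `split` with values in
#' `{training, verification, validation}`.
#'
#' @param split A `study_split`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  blk <- function(ids, nm) if (length(ids))
    data.frame(sample_id = ids, split = nm)
  df <- rbind(blk(split$training_ids, "training"),
              blk(split$verification_ids, "verification"),
              blk(split$validation_ids, "validation"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a split manifest written by [write_split_manifest()]
#'
#' @param path Manifest path.
#' @return A `study_split` (seed `NA`, unknown from a manifest).
#' @export
read_split_manifest <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  stopifnot(all(c("sample_id", "split") %in% names(df)))
  bad <- setdiff(unique(df$split), c("training", "verification", "validation"))
  if (length(bad)) stop("unknown split label(s): ", paste(bad, collapse = ", "))
  split <- list(
    training_ids = sort(df$sample_id[df$split == "training"]),
    verification_ids = sort(df$sample_id[df$split == "verification"]),
    validation_ids = sort(df$sample_id[df$split == "validation"]),
    seed = NA_integer_)
  class(split) <- "study_split"
  split
}
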