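#' ECG abnormality class labels
#'
#' The six target abnormalities, in canonical order: first-degree
#' atrioventricular block (1dAVb), right/left bundle branch block
#' (RBBB/LBBB), sinus bradycardia (SB), atrial fibrillation (AF) and sinus
#' tachycardia (ST).
#' @export
ECG_CLASSES <- c("1dAVb", "RBBB", "LBBB", "SB", "AF", "ST")

#' Standard 12-lead names in canonical order
#' @export
ECG_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
               "V1", "V2", "V3", "V4", "V5", "V6")

#' Construct an ECG recording
#'
#' A `recording` is the raw-data container of the pipeline: a channels-by-
#' samples matrix of millivolt-scale traces, its sampling rate, and an
#' optional multi-label annotation over [ECG_CLASSES]. Records with missing
#' readings are rejected at construction, mirroring the exclusion of entries
#' with missing readings during dataset cleaning.
#'
#' @param signal numeric matrix, `n_channels x n_samples`.
#' @param fs sampling rate in Hz (positive scalar).
#' @param labels optional 0/1 vector of length 6 (order of [ECG_CLASSES]).
#' @param record_id opaque identifier string.
#' @return An object of class `recording`.
#' @export
new_recording <- function(signal, fs, labels = NULL, record_id = "rec") {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stopf("`signal` must be a numeric matrix (channels x samples)")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stopf("`fs` must be a positive scalar sampling rate in Hz")
  }
  if (anyNA(signal) || !all(is.finite(signal))) {
    stopf("invalid input: recording '%s' contains missing or non-finite readings", record_id)
  }
  if (!is.null(labels)) {
    labels <- as.numeric(labels)
    if (length(labels) != length(ECG_CLASSES) || !all(labels %in% c(0, 1))) {
      stopf("`labels` must be a 0/1 vector of length %d", length(ECG_CLASSES))
    }
    names(labels) <- ECG_CLASSES
  }
  structure(
    list(signal = signal, fs = as.numeric(fs), labels = labels,
         record_id = as.character(record_id)),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording '%s'> %d channels x %d samples @ %g Hz (%.2f s)\n",
              x$record_id, nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs))
  if (!is.null(x$labels)) {
    pos <- names(x$labels)[x$labels == 1]
    cat("  labels:", if (length(pos)) paste(pos, collapse = ", ") else "none (normal)", "\n")
  }
  invisible(x)
}

#' @export
is_recording <- function(x) inherits(x, "recording")

# Validate a recording for full-pipeline use (12 leads).
check_pipeline_recording <- function(rec) {
  if (!is_recording(rec)) stopf("expected a `recording` object")
  if (nrow(rec$signal) != 12L) {
    stopf("pipeline recordings must have 12 channels, got %d", nrow(rec$signal))
  }
  invisible(rec)
}

#' Extract the label matrix of a record set
#'
#' @param records list of `recording` objects, all labeled.
#' @return numeric matrix `n_records x 6` of 0/1 labels.
#' @export
label_matrix <- function(records) {
  labs <- lapply(records, function(r) {
    if (is.null(r$labels)) stopf("record '%s' has no labels", r$record_id)
    r$labels
  })
  out <- do.call(rbind, labs)
  rownames(out) <- vapply(records, function(r) r$record_id, character(1))
  out
}
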