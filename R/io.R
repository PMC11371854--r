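#' Write a recording as a WFDB record pair
#'
#' Minimal WFDB writer: format-16 (little-endian int16) interleaved
#' samples in `<record>.dat`, header in `<record>.hea` with per-signal
#' gain and lead description, and the label vector as a header comment.
#'
#' @param rec a recording.
#' @param path record path without extension.
#' @param gain ADC units per millivolt.
#' @export
write_wfdb <- function(rec, path, gain = 200) {
  if (!is_recording(rec)) stopf("`rec` must be a recording")
  n_sig <- nrow(rec$signal); n_samp <- ncol(rec$signal)
  name <- basename(path)
  adc <- round(rec$signal * gain)
  if (any(abs(adc) > 32767)) stopf("signal exceeds int16 range at gain %g", gain)
  leads <- if (n_sig == 12) ECG_LEADS else sprintf("CH%d", seq_len(n_sig))
  hdr <- c(sprintf("%s %d %g %d", name, n_sig, rec$fs, n_samp),
           sprintf("%s.dat 16 %g/mV 16 0 0 0 0 %s", name, gain, leads))
  if (!is.null(rec$labels)) {
    hdr <- c(hdr, paste("# labels:", paste(rec$labels, collapse = ",")))
  }
  writeLines(hdr, paste0(path, ".hea"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(adc[seq_len(n_sig * n_samp)]), con, size = 2, endian = "little")
  invisible(path)
}

#' Read an ECG record
#'
#' Supported formats: WFDB format-16 record pairs (`.hea`/`.dat`) and the
#' package's CSV layout (see [write_record_csv()]). Twelve-lead records
#' are canonicalized to the standard lead order I, II, III, aVR, aVL,
#' aVF, V1-V6 when the stored lead names are recognizable; records with
#' missing readings are rejected.
#'
#' @param path record path; for WFDB, without extension or pointing at
#'   the `.hea` file.
#' @param format `"wfdb"` or `"csv"` (guessed from the path by default).
#' @export
read_record <- function(path, format = c("auto", "wfdb", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path)) "csv" else "wfdb"
  }
  switch(format, wfdb = read_wfdb(path), csv = read_record_csv(path))
}

read_wfdb <- function(path) {
  path <- sub("\\.hea$", "", path)
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stopf("unknown record: header file '%s' not found", hea)
  lines <- readLines(hea)
  lab_line <- grep("^#\\s*labels:", lines, value = TRUE)
  lines_ns <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines_ns[1]), "\\s+")[[1]]
  if (length(top) < 4) stopf("corrupt WFDB header '%s'", hea)
  n_sig <- as.integer(top[2]); fs <- as.numeric(top[3]); n_samp <- as.integer(top[4])
  sig_lines <- lines_ns[1 + seq_len(n_sig)]
  fields <- lapply(sig_lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  fmts <- vapply(fields, `[`, character(1), 2)
  if (!all(fmts == "16")) stopf("unsupported WFDB format(s): %s", paste(unique(fmts), collapse = ","))
  gains <- vapply(fields, function(f) as.numeric(sub("[(/].*$", "", f[3])), numeric(1))
  leads <- vapply(fields, function(f) f[length(f)], character(1))
  dat <- paste0(path, ".dat")
  if (!file.exists(dat)) stopf("corrupt record: data file '%s' not found", dat)
  raw <- readBin(dat, "integer", n = n_sig * n_samp, size = 2, endian = "little")
  if (length(raw) < n_sig * n_samp) stopf("corrupt record: '%s' is truncated", dat)
  sig <- matrix(raw, n_sig, n_samp) / gains
  rownames(sig) <- leads
  labels <- NULL
  if (length(lab_line)) {
    labels <- as.numeric(strsplit(sub("^#\\s*labels:\\s*", "", lab_line[1]), ",")[[1]])
  }
  canonicalize_leads(new_recording(sig, fs, labels, basename(path)))
}

# Reorder a 12-channel recording into the standard lead sequence when the
# stored names are recognizable; reject records with missing leads.
canonicalize_leads <- function(rec) {
  nms <- rownames(rec$signal)
  if (is.null(nms) || nrow(rec$signal) != 12) return(rec)
  up <- toupper(trimws(nms))
  std <- toupper(ECG_LEADS)
  if (all(std %in% up)) {
    ord <- match(std, up)
    sig <- rec$signal[ord, , drop = FALSE]
    rownames(sig) <- ECG_LEADS
    return(new_recording(sig, rec$fs, rec$labels, rec$record_id))
  }
  if (any(grepl("^(V[1-6]|AV[RLF]|I{1,3})$", up)) && !all(std %in% up)) {
    stopf("record '%s' is missing standard leads: %s", rec$record_id,
          paste(setdiff(std, up), collapse = ", "))
  }
  rec
}

#' Write / read a recording as CSV
#'
#' Plain-text adapter: a comment line holds the sampling rate, record id
#' and labels; the table has one column per lead, one row per sample.
#'
#' @param rec a recording.
#' @param path file path ending in `.csv`.
#' @export
write_record_csv <- function(rec, path) {
  hdr <- sprintf("# fs=%g id=%s labels=%s", rec$fs, rec$record_id,
                 if (is.null(rec$labels)) "NA" else paste(rec$labels, collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  nms <- rownames(rec$signal) %||% if (nrow(rec$signal) == 12) ECG_LEADS else
    sprintf("CH%d", seq_len(nrow(rec$signal)))
  utils::write.csv(stats::setNames(as.data.frame(t(rec$signal)), nms), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_record_csv
#' @export
read_record_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^#\\s*fs=", first)) stopf("corrupt CSV record '%s': missing metadata line", path)
  meta <- regmatches(first, gregexpr("[a-z]+=[^ ]+", first))[[1]]
  kv <- stats::setNames(sub("^[a-z]+=", "", meta), sub("=.*$", "", meta))
  df <- utils::read.csv(path, comment.char = "#")
  sig <- t(as.matrix(df))
  labels <- if (identical(kv[["labels"]], "NA")) NULL else
    as.numeric(strsplit(kv[["labels"]], ",")[[1]])
  canonicalize_leads(new_recording(sig, as.numeric(kv[["fs"]]),
                                   labels, kv[["id"]] %||% basename(path)))
}

#' Save / load pipeline artifacts
#'
#' Serialized container (RDS) for datasets, preprocessed tensors and
#' trained models; every artifact embeds a format stamp and the resolved
#' configuration it was produced with.
#'
#' @param object the artifact.
#' @param path file path.
#' @param config optional resolved configuration to embed.
#' @export
save_artifact <- function(object, path, config = NULL) {
  saveRDS(list(format = "ncpecg-artifact-v1", created = as.character(Sys.time()),
               config = config, object = object), path)
  invisible(path)
}

#' @rdname save_artifact
#' @export
load_artifact <- function(path) {
  x <- readRDS(path)
  if (!is.list(x) || !identical(x$format, "ncpecg-artifact-v1")) {
    stopf("'%s' is not an ncpecg artifact", path)
  }
  x$object
}

#' Write an evaluation report or robustness curve as JSON
#'
#' @param report an `eval_report` or `robustness_curve`.
#' @param path output path.
#' @param config optional resolved run configuration to embed.
#' @export
write_report_json <- function(report, path, config = NULL) {
  payload <- if (inherits(report, "eval_report")) {
    list(type = "eval_report", threshold = report$threshold,
         n_records = report$n_records,
         per_class = report$per_class, macro = report$macro)
  } else if (inherits(report, "robustness_curve")) {
    list(type = "robustness_curve", kind = report$kind, table = report$table)
  } else {
    stopf("unsupported report class: %s", paste(class(report), collapse = "/"))
  }
  payload$config <- config
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_run_config()
  utils::modifyList(defaults, cfg)
}

#' @rdname read_run_config
#' @param cfg nested configuration list.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

default_run_config <- function() {
  list(
    seed = 1,
    synth = list(n_records = 700, fs = 400, duration_s = 10, multilabel_rate = 0.1,
                 noise_floor_std = 0.02),
    preprocess = list(low_hz = 0.5, high_hz = 40, order = 4, window_len = 128,
                      hop = 64, window_fn = "hann", target_fs = 500, target_len = 4096),
    model = list(variant = "cltc", conv_filters = 8, kernel_size = 3, n_sensory = 75,
                 n_inter = 6, n_command = 8, n_motor = 6, delta = 1, n_unfold = 6),
    train = list(batch_size = 128, epochs = 300, learning_rate = 0.01,
                 positive_duplication_factor = 2, validation_fraction = 0.2),
    robustness = list(noise_std = 0.1, k_range = 1:6, n_draws = 20)
  )
}
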