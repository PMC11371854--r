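#' Add white noise to selected channels
#'
#' Adds i.i.d. zero-mean Gaussian noise of the given standard deviation
#' samplewise to the listed channels (raw signal units, i.e. millivolts);
#' other channels are returned bit-identical. Deterministic under `seed`;
#' the input recording is never modified in place.
#'
#' @param rec a recording.
#' @param channels 1-based channel indices to perturb.
#' @param std noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @export
add_white_noise <- function(rec, channels = seq_len(nrow(rec$signal)), std = 0.1, seed = 1) {
  if (!is_recording(rec)) stopf("`rec` must be a recording")
  if (!is.numeric(std) || std < 0) stopf("`std` must be non-negative")
  check_channels(rec, channels)
  if (std == 0 || length(channels) == 0) return(rec)
  sig <- rec$signal
  with_seed(seed, {
    for (ch in channels) {
      sig[ch, ] <- sig[ch, ] + stats::rnorm(ncol(sig), 0, std)
    }
  })
  new_recording(sig, rec$fs, rec$labels, rec$record_id)
}

#' Blank (zero out) selected channels
#'
#' @param rec a recording.
#' @param channels 1-based channel indices to set to zero.
#' @export
blank_channels <- function(rec, channels) {
  if (!is_recording(rec)) stopf("`rec` must be a recording")
  check_channels(rec, channels)
  if (length(channels) == 0) return(rec)
  sig <- rec$signal
  sig[channels, ] <- 0
  new_recording(sig, rec$fs, rec$labels, rec$record_id)
}

check_channels <- function(rec, channels) {
  if (length(channels) && (any(channels < 1) || any(channels > nrow(rec$signal)) ||
                           any(channels != round(channels)))) {
    stopf("channel indices must be integers in 1..%d", nrow(rec$signal))
  }
  invisible(channels)
}

#' Per-channel white-noise sweep
#'
#' One condition per channel: every record gets noise of standard
#' deviation `std` on exactly that channel (applied to the raw recording
#' before preprocessing), then the model is evaluated. Reports macro F1
#' and AUROC per condition.
#'
#' @param model an `ncp_model` or scoring function (see [predict_scores()]).
#' @param records labeled recordings.
#' @param std noise standard deviation.
#' @param seed RNG seed (one derived seed per condition/record).
#' @param threshold operating threshold for F1.
#' @return A `robustness_curve` with one row per channel.
#' @export
noise_sweep <- function(model, records, std = 0.1, seed = 1, threshold = 0.5) {
  n_ch <- nrow(records[[1]]$signal)
  rows <- lapply(seq_len(n_ch), function(ch) {
    pert <- lapply(seq_along(records), function(i) {
      add_white_noise(records[[i]], channels = ch, std = std,
                      seed = derive_seed(seed, paste0("noise", ch, "_", i)))
    })
    rep <- evaluate_model(model, pert, threshold = threshold)
    data.frame(condition = sprintf("noise_ch%02d", ch), channel = ch,
               macro_f1 = rep$macro$f1, macro_auroc = rep$macro$auroc)
  })
  structure(list(kind = "noise", std = std, seed = seed,
                 table = do.call(rbind, rows)),
            class = "robustness_curve")
}

#' Single-channel blanking sweep
#'
#' One condition per channel: that channel is zeroed on every record, the
#' model evaluated, and macro F1/AUROC reported.
#'
#' @inheritParams noise_sweep
#' @export
blanking_sweep <- function(model, records, threshold = 0.5) {
  n_ch <- nrow(records[[1]]$signal)
  rows <- lapply(seq_len(n_ch), function(ch) {
    pert <- lapply(records, blank_channels, channels = ch)
    rep <- evaluate_model(model, pert, threshold = threshold)
    data.frame(condition = sprintf("blank_ch%02d", ch), channel = ch,
               macro_f1 = rep$macro$f1, macro_auroc = rep$macro$auroc)
  })
  structure(list(kind = "blank_single", table = do.call(rbind, rows)),
            class = "robustness_curve")
}

#' Progressive random multi-channel blanking sweep
#'
#' For each `k` in `k_range`, draws `n_draws` random k-subsets of the
#' channels (without replacement within a draw), blanks them on every
#' record, evaluates, and averages macro F1/AUROC over the draws. `k = 0`
#' (if included) is the unperturbed control.
#'
#' @inheritParams noise_sweep
#' @param k_range numbers of channels to blank.
#' @param n_draws random channel subsets per `k`.
#' @return A `robustness_curve` with one row per `k`.
#' @export
progressive_blanking_sweep <- function(model, records, k_range = 1:6, n_draws = 20,
                                       seed = 1, threshold = 0.5) {
  if (!is_count(n_draws)) stopf("`n_draws` must be a positive integer")
  n_ch <- nrow(records[[1]]$signal)
  if (any(k_range > n_ch)) stopf("cannot blank more than %d channels", n_ch)
  rows <- lapply(k_range, function(k) {
    if (k == 0) {
      rep <- evaluate_model(model, records, threshold = threshold)
      return(data.frame(condition = "blank_k0", k = 0, n_draws = 1L,
                        macro_f1 = rep$macro$f1, macro_auroc = rep$macro$auroc))
    }
    f1s <- numeric(n_draws); aucs <- numeric(n_draws)
    for (d in seq_len(n_draws)) {
      chans <- with_seed(derive_seed(seed, paste0("k", k, "d", d)),
                         sample(n_ch, k))
      pert <- lapply(records, blank_channels, channels = chans)
      rep <- evaluate_model(model, pert, threshold = threshold)
      f1s[d] <- rep$macro$f1; aucs[d] <- rep$macro$auroc
    }
    data.frame(condition = sprintf("blank_k%d", k), k = k, n_draws = n_draws,
               macro_f1 = mean(f1s), macro_auroc = mean(aucs))
  })
  structure(list(kind = "blank_progressive", seed = seed,
                 table = do.call(rbind, rows)),
            class = "robustness_curve")
}

#' @export
print.robustness_curve <- function(x, ...) {
  cat(sprintf("<robustness_curve: %s>\n", x$kind))
  print(x$table, row.names = FALSE)
  invisible(x)
}
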