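# Shared fixtures: all built in code, no stored data.

# 12-channel recording holding the same deterministic waveform per channel.
sine_recording <- function(freq_hz, fs = 500, dur_s = 10, amp = 1, n_ch = 12,
                           labels = NULL) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  sig <- matrix(rep(amp * sin(2 * pi * freq_hz * t), each = n_ch), n_ch)
  new_recording(sig, fs, labels, sprintf("sine%g", freq_hz))
}

rms <- function(x) sqrt(mean(x^2))

# Small wiring/model configuration so unit tests stay fast.
tiny_wiring <- function(...) {
  wiring_config(n_sensory = 6, n_inter = 4, n_command = 3, n_motor = 2,
                fanout_per_source = 2, ...)
}

tiny_model_config <- function(variant = "cltc", ...) {
  model_config(variant = variant, conv_filters = 3, kernel_size = 3,
               n_sensory = 6, wiring = tiny_wiring(), n_classes = 2,
               n_leads = 4, n_unfold = 2, ...)
}

# Small but 12-lead/6-class model that accepts preprocessed synth records.
tiny_model_config_12 <- function(variant = "cltc", ...) {
  model_config(variant = variant, conv_filters = 2, kernel_size = 3,
               n_sensory = 8,
               wiring = wiring_config(n_sensory = 8, n_inter = 4,
                                      n_command = 4, n_motor = 6,
                                      fanout_per_source = 2),
               n_classes = 6, n_leads = 12, n_unfold = 2, ...)
}

# Independent R-peak detector used as an oracle against generator
# fiducials. Pan-Tompkins-style: the QRS has a far steeper slope than the
# P/T waves, so peaks of the smoothed SQUARED derivative of lead II above
# half its maximum, separated by a refractory distance, mark the beats
# (squaring keeps the QRS/T contrast high even for wide, shallow-sloped
# bundle-branch-block complexes).
detect_r_peaks <- function(rec, lead = 2, min_dist_s = 0.25) {
  x <- rec$signal[lead, ]
  e <- (diff(x) * rec$fs)^2
  k <- max(3L, round(0.03 * rec$fs))
  e <- as.numeric(stats::filter(e, rep(1 / k, k), sides = 2))
  e[is.na(e)] <- 0
  thr <- 0.5 * max(e)
  n <- length(e)
  cand <- which(e > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[e[cand] >= e[cand - 1] & e[cand] >= e[cand + 1]]
  peaks <- integer(0)
  for (i in cand) {
    if (!length(peaks) || (i - peaks[length(peaks)]) / rec$fs >= min_dist_s) {
      peaks <- c(peaks, i)
    } else if (e[i] > e[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- i
    }
  }
  (peaks - 1) / rec$fs
}

# Score matrix labels for metric tests.
toy_scores <- function() {
  list(scores = matrix(c(0.9, 0.8, 0.7, 0.4, 0.3, 0.1,
                         0.2, 0.9, 0.6, 0.5, 0.8, 0.3), 6, 2),
       y = matrix(c(1, 1, 1, 0, 0, 0,
                    0, 1, 1, 0, 1, 0), 6, 2))
}

# "Oracle" scoring function that looks only at channel `ch` of the raw
# recordings: per-class score driven by the channel's RMS amplitude,
# centered so scores straddle the 0.5 operating threshold.
single_channel_oracle <- function(ch, n_classes = 6) {
  function(records) {
    s <- vapply(records, function(r) rms(r$signal[ch, ]), numeric(1))
    s <- 1 / (1 + exp(-10 * (s - 0.2)))
    matrix(rep(s, n_classes), ncol = n_classes)
  }
}

# Printed validation/generalization tables (percent scale) used by the
# metric-consistency checks.
cltc_validation_table <- function() {
  data.frame(
    class = c("1dAVb", "RBBB", "LBBB", "SB", "AF", "ST"),
    precision = c(71.2, 92.5, 91.2, 89.3, 77.5, 92.5),
    recall = c(52.7, 84.0, 93.6, 92.6, 70.5, 88.7),
    f1 = c(60.6, 88.1, 92.4, 90.9, 73.8, 90.6),
    auroc = c(88.1, 97.2, 99.1, 99.0, 94.1, 99.3))
}

cltc_validation_macro <- function() {
  c(precision = 85.7, recall = 80.3, f1 = 82.7, auroc = 96.1)
}

ccfc_validation_table <- function() {
  data.frame(
    class = c("1dAVb", "RBBB", "LBBB", "SB", "AF", "ST"),
    precision = c(75.9, 92.3, 88.9, 89.2, 78.7, 90.4),
    recall = c(52.2, 82.9, 93.2, 92.9, 71.3, 91.5),
    f1 = c(61.8, 87.3, 91.0, 91.0, 74.8, 90.9),
    auroc = c(89.3, 97.1, 99.1, 99.0, 93.7, 99.3))
}

ccfc_validation_macro <- function() {
  c(precision = 85.9, recall = 80.6, f1 = 82.8, auroc = 96.3)
}

cltc_generalization_table <- function() {
  data.frame(
    class = c("1dAVb", "RBBB", "LBBB", "AF"),
    precision = c(47.8, 91.5, 89.0, 50.8),
    recall = c(65.2, 60.8, 82.6, 92.9),
    f1 = c(55.2, 73.0, 85.7, 65.7),
    auroc = c(86.7, 83.8, 96.6, 93.4))
}

cltc_generalization_macro <- function() {
  c(precision = 69.8, recall = 75.4, f1 = 69.9, auroc = 90.1)
}

ccfc_generalization_table <- function() {
  data.frame(
    class = c("1dAVb", "RBBB", "LBBB", "AF"),
    precision = c(72.9, 90.4, 88.2, 50.6),
    recall = c(57.9, 61.0, 82.6, 94.1),
    f1 = c(64.6, 72.9, 85.3, 65.8),
    auroc = c(88.9, 84.7, 97.2, 94.4))
}

ccfc_generalization_macro <- function() {
  c(precision = 75.5, recall = 73.9, f1 = 72.1, auroc = 91.3)
}
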