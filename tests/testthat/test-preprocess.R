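test_that("band-pass filter passes in-band tones and rejects powerline noise", {
  spec <- filter_spec()
  # expected attenuations from the designed transfer function (zero-phase
  # application squares the one-pass magnitude)
  h50 <- bandpass_response(spec, 500, 50)^2
  h10 <- bandpass_response(spec, 500, 10)^2
  expect_lt(h50, 0.2)
  expect_gt(h10, 0.95)

  out50 <- bandpass_filter(sine_recording(50), spec)
  in50 <- sine_recording(50)
  expect_lt(rms(out50$signal[1, ]) / rms(in50$signal[1, ]), 0.2)

  out10 <- bandpass_filter(sine_recording(10), spec)
  mid <- 1000:4000  # away from filtfilt edge transients
  expect_equal(rms(out10$signal[1, mid]) / rms(sine_recording(10)$signal[1, mid]),
               sqrt(h10), tolerance = 0.05)

  zero <- new_recording(matrix(0, 12, 5000), 500)
  expect_equal(bandpass_filter(zero, spec)$signal, zero$signal)
})

test_that("filtering is linear and rejects invalid configurations", {
  a <- sine_recording(7, dur_s = 4); b <- sine_recording(19, dur_s = 4)
  spec <- filter_spec()
  comb <- new_recording(2 * a$signal + 3 * b$signal, 500)
  lhs <- bandpass_filter(comb, spec)$signal
  rhs <- 2 * bandpass_filter(a, spec)$signal + 3 * bandpass_filter(b, spec)$signal
  expect_equal(lhs, rhs, tolerance = 1e-9)

  # powerline magnitude strictly below in-band magnitude
  expect_lt(bandpass_response(spec, 500, 50), bandpass_response(spec, 500, 10))

  expect_error(bandpass_filter(sine_recording(10, fs = 70), filter_spec(high_hz = 40)),
               "invalid filter spec")
  expect_error(new_recording(matrix(c(NA, rep(0, 23)), 2), 500), "missing")
})

test_that("resampling preserves tone shape and obeys the length contract", {
  rec <- sine_recording(5, fs = 400, dur_s = 10)
  out <- resample_recording(rec, 500)
  expect_equal(ncol(out$signal), 5000)
  expect_equal(out$fs, 500)
  tnew <- (seq_len(5000) - 1) / 500
  core <- 250:4750
  expect_lt(max(abs(out$signal[1, core] - sin(2 * pi * 5 * tnew[core]))), 1e-3)

  same <- resample_recording(rec, 400)
  expect_identical(same$signal, rec$signal)
  expect_error(resample_recording(rec, 1e-4), "empty")
})

test_that("length normalization truncates, pads and is idempotent", {
  long <- new_recording(matrix(rnorm(12 * 5000), 12), 500)
  out <- normalize_length(long)
  expect_identical(dim(out$signal), c(12L, 4096L))
  expect_identical(out$signal, long$signal[, 1:4096])

  exact <- new_recording(matrix(rnorm(12 * 4096), 12), 500)
  expect_identical(normalize_length(exact)$signal, exact$signal)

  short <- new_recording(matrix(rnorm(12 * 3000), 12), 500)
  pad <- normalize_length(short)
  expect_identical(pad$signal[, 1:3000], short$signal)
  expect_true(all(pad$signal[, 3001:4096] == 0))

  expect_identical(normalize_length(normalize_length(long))$signal, out$signal)
})

test_that("STFT matches windowed-DFT identities", {
  # unit impulse with a rectangular window: flat unit spectrum
  imp <- matrix(0, 1, 64); imp[1, 1] <- 1
  rec <- new_recording(imp, 500)
  cfg <- stft_config(window_len = 64, hop = 64, window_fn = "rectangular")
  sp <- stft(rec, cfg)
  expect_equal(dim(sp$values), c(1L, 33L, 1L))
  expect_equal(as.numeric(sp$values[1, , 1]), rep(1, 33))

  # zero signal -> zero spectrogram
  z <- stft(new_recording(matrix(0, 12, 512), 500), stft_config())
  expect_true(all(z$values == 0))

  # bin-aligned sinusoid concentrates energy in its bin
  fs <- 500; wl <- 128; k0 <- 8
  f0 <- k0 * fs / wl
  rec2 <- sine_recording(f0, fs = fs, dur_s = 2, n_ch = 1)
  sp2 <- stft(rec2, stft_config(window_len = wl, hop = wl, window_fn = "rectangular"))
  en <- sp2$values[1, , 1]^2
  expect_gt(en[k0 + 1] / sum(en), 0.99)

  # frame-count contract and error on short input
  sp3 <- stft(new_recording(matrix(rnorm(4096), 1), 500), stft_config(128, 64))
  expect_equal(dim(sp3$values)[3], (4096 - 128) %/% 64 + 1)
  expect_error(stft(new_recording(matrix(0, 1, 100), 500), stft_config(128, 64)),
               "exceeds")
})

test_that("STFT with rectangular non-overlapping windows satisfies Parseval", {
  set.seed(5)
  rec <- new_recording(matrix(rnorm(1024), 1), 500)
  wl <- 128
  sp <- stft(rec, stft_config(wl, wl, "rectangular", output_mode = "complex"))
  for (f in seq_len(dim(sp$values)[3])) {
    td <- sum(rec$signal[1, ((f - 1) * wl + 1):(f * wl)]^2)
    fd <- sum(Mod(sp$values[1, , f])^2) / wl
    expect_equal(fd, td, tolerance = 1e-6)
  }
})

test_that("pipeline composes deterministically with config-determined shape", {
  set.seed(9)
  ds <- generate_dataset(synth_config(n_records = 2, seed = 42))
  sp1 <- preprocess_pipeline(ds$records[[1]])
  expect_equal(dim(sp1$values), c(12L, 65L, 63L))
  sp1b <- preprocess_pipeline(ds$records[[1]])
  expect_identical(sp1$values, sp1b$values)
  # output shape depends only on configuration, not signal content
  sp2 <- preprocess_pipeline(ds$records[[2]])
  expect_identical(dim(sp1$values), dim(sp2$values))
  # missing readings are rejected before entering the pipeline
  expect_error(new_recording(matrix(NaN, 12, 4000), 400), "missing or non-finite")
})
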