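#' Model configuration
#'
#' Assembles the end-to-end classifier: a single ConvLSTM layer extracts
#' features from the spectrogram frame sequence (the 12 leads enter as
#' input channels, the frequency bins form the spatial grid, STFT frames
#' form the time axis); the layer's per-frame spatial output is flattened
#' and densely connected to the 75 sensory neurons of the NCP network, and
#' the chosen continuous-time cell (LTC for the CLTC variant, CfC for
#' CCfC) unrolls across frames. The final motor state passes through a sigmoid,
#' one independent score per abnormality class (no softmax: labels are not
#' mutually exclusive).
#'
#' @param variant `"cltc"` (LTC cell) or `"ccfc"` (CfC cell).
#' @param conv_filters,kernel_size ConvLSTM hidden channels and kernel
#'   extent along the frequency axis.
#' @param n_sensory sensory neurons fed by the dense projection.
#' @param wiring a [wiring_config()]; its motor count must equal `n_classes`.
#' @param n_classes output classes (fixed head activation: sigmoid).
#' @param n_leads input channels (12-lead ECG).
#' @param max_freq_hz upper edge of the spectrogram band fed to the
#'   network. Frequencies above the band-pass cutoff carry no signal
#'   after filtering, so bins above this edge are cropped before the
#'   ConvLSTM (set to `Inf` to keep all bins).
#' @param n_freq_bins number of frequency bins after cropping; fixes the
#'   flattened feature width of the dense projection. Computed from
#'   `max_freq_hz` and the STFT configuration by default.
#' @param delta,n_unfold integration step and sub-steps of the LTC solver
#'   (`n_unfold` is ignored by the CfC variant).
#' @param preprocess list of preprocessing settings
#'   (`filter`, `stft_cfg`, `target_fs`, `target_len`) records are pushed
#'   through before entering the network.
#' @export
model_config <- function(variant = c("cltc", "ccfc"), conv_filters = 8, kernel_size = 3,
                         n_sensory = 75, wiring = wiring_config(n_sensory = n_sensory),
                         n_classes = 6, n_leads = 12, max_freq_hz = 40,
                         n_freq_bins = NULL, delta = 1, n_unfold = 6,
                         preprocess = list(filter = filter_spec(), stft_cfg = stft_config(),
                                           target_fs = 500, target_len = 4096)) {
  variant <- match.arg(variant)
  if (is.null(n_freq_bins)) {
    full <- preprocess$stft_cfg$window_len %/% 2L + 1L
    bw <- preprocess$target_fs / preprocess$stft_cfg$window_len
    n_freq_bins <- if (is.finite(max_freq_hz)) {
      min(full, floor(max_freq_hz / bw) + 1L)
    } else full
  }
  if (wiring$n_motor != n_classes) {
    stopf("configuration error: wiring has %d motor neurons but n_classes = %d",
          wiring$n_motor, n_classes)
  }
  if (wiring$n_sensory != n_sensory) {
    stopf("configuration error: wiring has %d sensory neurons but n_sensory = %d",
          wiring$n_sensory, n_sensory)
  }
  if (kernel_size %% 2 != 1) stopf("`kernel_size` must be odd")
  structure(list(variant = variant, conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size), n_sensory = as.integer(n_sensory),
                 wiring = wiring, n_classes = as.integer(n_classes),
                 n_leads = as.integer(n_leads), max_freq_hz = max_freq_hz,
                 n_freq_bins = as.integer(n_freq_bins), delta = delta,
                 n_unfold = as.integer(n_unfold), preprocess = preprocess),
            class = "model_config")
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Build a CLTC or CCfC model
#'
#' Deterministic under `seed`: repeated builds with the same configuration
#' and seed produce identical initial parameters. The two variants share
#' the feature extractor and head structure and differ only in the
#' recurrent cell.
#'
#' @param cfg a [model_config()].
#' @param seed RNG seed for wiring and parameter initialization.
#' @return An object of class `ncp_model`.
#' @export
build_model <- function(cfg = model_config(), seed = 1) {
  if (!inherits(cfg, "model_config")) stopf("`cfg` must be a model_config")
  K <- cfg$conv_filters
  C <- cfg$n_leads
  ks <- cfg$kernel_size
  wiring <- build_wiring(cfg$wiring, seed = derive_seed(seed, "wiring"))
  cell <- if (cfg$variant == "cltc") {
    ltc_params(wiring, delta = cfg$delta, n_unfold = cfg$n_unfold,
               seed = derive_seed(seed, "cell"))
  } else {
    cfc_params(wiring, delta = cfg$delta, seed = derive_seed(seed, "cell"))
  }
  model <- with_seed(derive_seed(seed, "extractor"), {
    # positive forget-gate bias: the cell state starts with a ~0.88/frame
    # retention so rhythm information persists across roughly a second
    conv <- list(Wx = glorot(ks * C, 4 * K), Wh = glorot(ks * K, 4 * K),
                 b = c(rep(0, K), rep(2, K), rep(0, 2 * K)))
    dense <- list(W = glorot(cfg$n_freq_bins * K, cfg$n_sensory),
                  b = rep(0, cfg$n_sensory))
    list(conv = conv, dense = dense)
  })
  m <- structure(list(config = cfg, wiring = wiring, cell = cell,
                      conv = model$conv, dense = model$dense,
                      norm = list(center = 0, scale = 1), seed = seed),
                 class = c(paste0(cfg$variant, "_model"), "ncp_model"))
  m$n_params <- n_model_params(m)
  m
}

#' Number of trainable parameters of a model
#' @param model an `ncp_model`.
#' @export
n_model_params <- function(model) {
  length(model$conv$Wx) + length(model$conv$Wh) + length(model$conv$b) +
    length(model$dense$W) + length(model$dense$b) + n_cell_params(model$cell)
}

#' @export
print.ncp_model <- function(x, ...) {
  lay <- x$cell$layout
  cat(sprintf("<%s model> ConvLSTM(%d filters, kernel %d) -> dense %d sensory -> NCP %d neurons -> %d sigmoid outputs\n",
              toupper(x$config$variant), x$config$conv_filters, x$config$kernel_size,
              x$config$n_sensory, lay$n_state, x$config$n_classes))
  cat(sprintf("  %d trainable parameters, %d synapses, seed %s\n",
              x$n_params, nrow(x$wiring$edges), format(x$seed)))
  invisible(x)
}

# im2col index structure for a (B, F) batch of 1-D frequency grids, shared
# across frames. Pad rows are zero.
conv_indices <- function(B, F_, ks) {
  half <- (ks - 1L) %/% 2L
  Fp <- F_ + 2L * half
  real <- as.vector(outer(half + seq_len(F_), (seq_len(B) - 1L) * Fp, `+`))
  shifts <- lapply(seq.int(-half, half), function(s) real + s)
  list(real = real, shifts = shifts, Fp = Fp, B = B, F_ = F_, half = half)
}

im2col <- function(M, ci, n_col) {
  pad <- matrix(0, ci$Fp * ci$B, n_col)
  pad[ci$real, ] <- M
  do.call(cbind, lapply(ci$shifts, function(ix) pad[ix, , drop = FALSE]))
}

col2im <- function(dcol, ci, n_col) {
  pad <- matrix(0, ci$Fp * ci$B, n_col)
  for (s in seq_along(ci$shifts)) {
    block <- dcol[, (s - 1L) * n_col + seq_len(n_col), drop = FALSE]
    ix <- ci$shifts[[s]]
    pad[ix, ] <- pad[ix, ] + block
  }
  pad[ci$real, , drop = FALSE]
}

# Apply the model's fixed input transform (log-magnitude compression and
# global standardization fitted at training time).
transform_input <- function(model, x) {
  (log1p(x) - model$norm$center) / model$norm$scale
}

# Crop spectrogram bins above the configured band edge: after the 0.5-40 Hz
# band-pass those bins are numerically empty, so the network never sees them.
crop_freq_bins <- function(model, x) {
  if (!is.finite(model$config$max_freq_hz)) return(x)
  bw <- model$config$preprocess$target_fs / model$config$preprocess$stft_cfg$window_len
  keep <- min(dim(x)[3], floor(model$config$max_freq_hz / bw) + 1L)
  if (keep < dim(x)[3]) x[, , seq_len(keep), , drop = FALSE] else x
}

# Full forward pass over a batch.
# x: array n_records x n_leads x n_freq x n_frames.
# Returns scores [N x n_classes]; with keep=TRUE also every intermediate
# needed by backprop.
forward_batch <- function(model, x, keep = FALSE) {
  stopifnot(length(dim(x)) == 4)
  x <- crop_freq_bins(model, x)
  N <- dim(x)[1]; C <- dim(x)[2]; F_ <- dim(x)[3]; Tn <- dim(x)[4]
  if (C != model$config$n_leads) {
    stopf("input has %d channels, model expects %d", C, model$config$n_leads)
  }
  if (F_ != model$config$n_freq_bins) {
    stopf("input has %d frequency bins after cropping, model expects %d",
          F_, model$config$n_freq_bins)
  }
  K <- model$config$conv_filters
  x <- transform_input(model, x)
  ci <- conv_indices(N, F_, model$config$kernel_size)
  h <- matrix(0, N * F_, K); cst <- matrix(0, N * F_, K)
  nr <- N * F_
  U_seq <- vector("list", Tn)
  cache <- if (keep) list(frames = vector("list", Tn), ci = ci, dims = dim(x)) else NULL
  for (t in seq_len(Tn)) {
    # frame input: rows (position within record, record), cols = leads
    xt <- array(x[, , , t], dim = c(N, C, F_))
    Ut <- matrix(aperm(xt, c(3, 1, 2)), nr, C)
    Xcol <- im2col(Ut, ci, C)
    Hcol <- im2col(h, ci, K)
    Z <- Xcol %*% model$conv$Wx + Hcol %*% model$conv$Wh
    Z <- Z + rep(model$conv$b, each = nr)
    gi <- 1 / (1 + exp(-Z[, seq_len(K), drop = FALSE]))
    gf <- 1 / (1 + exp(-Z[, K + seq_len(K), drop = FALSE]))
    go <- 1 / (1 + exp(-Z[, 2L * K + seq_len(K), drop = FALSE]))
    gc_ <- tanh(Z[, 3L * K + seq_len(K), drop = FALSE])
    c_prev <- cst
    cst <- gf * c_prev + gi * gc_
    tc <- tanh(cst)
    h_prev <- h
    h <- go * tc
    # flatten the spatial map: feat[b, (k-1)*F + p] = h[p + (b-1)*F, k]
    feat <- matrix(aperm(array(h, c(F_, N, K)), c(2, 1, 3)), N, F_ * K)
    pre_s <- feat %*% model$dense$W + rep(model$dense$b, each = N)
    S <- 1 / (1 + exp(-pre_s))
    U_seq[[t]] <- t(S)
    if (keep) {
      cache$frames[[t]] <- list(Ut = Ut, h_prev = h_prev, c_prev = c_prev,
                                gi = gi, gf = gf, go = go, gc = gc_,
                                tc = tc, feat = feat, S = S)
    }
  }
  cellf <- if (inherits(model$cell, "ltc_params")) {
    ltc_forward_seq(model$cell, U_seq, keep = keep)
  } else {
    cfc_forward_seq(model$cell, U_seq, keep = keep)
  }
  motor <- cellf$final[model$cell$layout$motor_idx, , drop = FALSE]
  scores <- t(1 / (1 + exp(-motor)))
  colnames(scores) <- ECG_CLASSES[seq_len(ncol(scores))]
  if (keep) {
    list(scores = scores, motor = motor, U_seq = U_seq,
         cell_cache = cellf$cache, conv_cache = cache)
  } else {
    list(scores = scores)
  }
}

# Backward pass. d_motor: gradient of the loss wrt the motor logits
# [n_classes x N]. Returns gradients shaped like the model parameters.
backward_batch <- function(model, fwd, d_motor) {
  K <- model$config$conv_filters
  lay <- model$cell$layout
  N <- ncol(fwd$U_seq[[1]])
  dX_final <- matrix(0, lay$n_state, N)
  dX_final[lay$motor_idx, ] <- d_motor
  cellb <- if (inherits(model$cell, "ltc_params")) {
    ltc_backward_seq(model$cell, fwd$U_seq, fwd$cell_cache, dX_final)
  } else {
    cfc_backward_seq(model$cell, fwd$U_seq, fwd$cell_cache, dX_final)
  }
  ci <- fwd$conv_cache$ci
  F_ <- ci$F_
  nr <- N * F_
  dWd <- model$dense$W * 0; dbd <- model$dense$b * 0
  dWx <- model$conv$Wx * 0; dWh <- model$conv$Wh * 0; db <- model$conv$b * 0
  dh_next <- matrix(0, nr, K); dc_next <- matrix(0, nr, K)
  for (t in rev(seq_along(fwd$U_seq))) {
    fc <- fwd$conv_cache$frames[[t]]
    dS <- t(cellb$dU_seq[[t]])                    # N x n_sensory
    dpre_s <- dS * fc$S * (1 - fc$S)
    dWd <- dWd + crossprod(fc$feat, dpre_s)
    dbd <- dbd + colSums(dpre_s)
    dfeat <- dpre_s %*% t(model$dense$W)          # N x (F*K)
    dh_feat <- matrix(aperm(array(dfeat, c(N, F_, K)), c(2, 1, 3)), nr, K)
    dh <- dh_next + dh_feat
    do_ <- dh * fc$tc
    dc <- dh * fc$go * (1 - fc$tc^2) + dc_next
    di <- dc * fc$gc
    df <- dc * fc$c_prev
    dgc <- dc * fc$gi
    dc_next <- dc * fc$gf
    dZ <- cbind(di * fc$gi * (1 - fc$gi),
                df * fc$gf * (1 - fc$gf),
                do_ * fc$go * (1 - fc$go),
                dgc * (1 - fc$gc^2))
    Xcol <- im2col(fc$Ut, ci, model$config$n_leads)
    Hcol <- im2col(fc$h_prev, ci, K)
    dWx <- dWx + crossprod(Xcol, dZ)
    dWh <- dWh + crossprod(Hcol, dZ)
    db <- db + colSums(dZ)
    dh_next <- col2im(dZ %*% t(model$conv$Wh), ci, K)
  }
  list(conv = list(Wx = dWx, Wh = dWh, b = db),
       dense = list(W = dWd, b = dbd),
       cell = cellb$grads)
}

#' Predict class scores for a batch of inputs
#'
#' Accepts either preprocessed input (the list returned by
#' [preprocess_dataset()], or a bare 4-D array) or a list of raw 12-lead
#' recordings, which are first pushed through the model's stored
#' preprocessing configuration. Inference is deterministic.
#'
#' @param model an `ncp_model`.
#' @param x input data (see above).
#' @param batch_size records per forward pass.
#' @return matrix `n_records x n_classes` of scores in (0, 1).
#' @export
predict_scores <- function(model, x, batch_size = 128) {
  if (is.function(model)) return(model(x))
  if (!inherits(model, "ncp_model")) stopf("`model` must be an ncp_model or a function")
  if (is.list(x) && !is.null(x$x)) x <- x$x
  if (is.list(x) && all(vapply(x, is_recording, logical(1)))) {
    pp <- model$config$preprocess
    x <- preprocess_dataset(x, filter = pp$filter, stft_cfg = pp$stft_cfg,
                            target_fs = pp$target_fs, target_len = pp$target_len)$x
  }
  N <- dim(x)[1]
  out <- matrix(0, N, model$config$n_classes)
  colnames(out) <- ECG_CLASSES[seq_len(ncol(out))]
  for (start in seq(1, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, N)
    out[idx, ] <- forward_batch(model, x[idx, , , , drop = FALSE])$scores
  }
  out
}

#' Binary cross-entropy over a multi-label score matrix
#'
#' Mean over records and classes of `-(y log p + (1-y) log(1-p))`, with
#' scores clipped away from 0 and 1 by `eps`.
#'
#' @param scores matrix of predicted scores in (0, 1).
#' @param y matrix of 0/1 labels, same shape.
#' @param eps clipping constant.
#' @export
bce_loss <- function(scores, y, eps = 1e-7) {
  p <- pmin(pmax(scores, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
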