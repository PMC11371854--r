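#' Training configuration
#'
#' Default protocol: Adam with learning rate 0.01 on the binary
#' cross-entropy loss, batch size 128, 300 epochs, positive-labeled
#' training instances duplicated twice (each appears three times), and a
#' stratified 80/20 train/validation split. Duplication is applied only to
#' the training partition, never to validation data.
#'
#' @param batch_size records per gradient step.
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param positive_duplication_factor extra copies of each positive-labeled
#'   training instance.
#' @param validation_fraction held-out share for [split_dataset()].
#' @param clip_norm global gradient-norm clip (numerical safeguard).
#' @param eps BCE score-clipping constant.
#' @param seed seed for shuffling (initialization is seeded in
#'   [build_model()]).
#' @export
train_config <- function(batch_size = 128, epochs = 300, learning_rate = 0.01,
                         positive_duplication_factor = 2, validation_fraction = 0.2,
                         clip_norm = 5, eps = 1e-7, seed = 1) {
  if (!is_count(batch_size) || !is_count(epochs)) {
    stopf("batch_size and epochs must be positive integers")
  }
  if (positive_duplication_factor < 0 ||
      positive_duplication_factor != round(positive_duplication_factor)) {
    stopf("positive_duplication_factor must be a non-negative integer")
  }
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 positive_duplication_factor = as.integer(positive_duplication_factor),
                 validation_fraction = validation_fraction,
                 clip_norm = clip_norm, eps = eps, seed = seed),
            class = "train_config")
}

#' Stratified train/validation split
#'
#' Disjoint partitions with the validation share equal to `fraction` up to
#' one record per stratum, stratified by the full label pattern so the
#' per-class positive rates of the validation set track the global rates.
#' Deterministic under `seed`.
#'
#' @param records list of labeled recordings.
#' @param fraction validation fraction in (0, 1).
#' @param seed RNG seed.
#' @return list with elements `train` and `validation` (lists of records).
#' @export
split_dataset <- function(records, fraction = 0.2, seed = 1) {
  if (length(records) < 5) stopf("need at least 5 records to split")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stopf("`fraction` must lie strictly between 0 and 1")
  }
  y <- label_matrix(records)
  pattern <- apply(y, 1, paste, collapse = "")
  pats <- unique(pattern)
  sizes <- vapply(pats, function(p) sum(pattern == p), numeric(1))
  # largest-remainder apportionment keeps the overall share at the target
  raw <- fraction * sizes
  quota <- floor(raw)
  rem <- round(fraction * length(records)) - sum(quota)
  if (rem > 0) {
    bump <- order(raw - quota, decreasing = TRUE)[seq_len(rem)]
    quota[bump] <- quota[bump] + 1
  }
  quota <- pmin(quota, sizes)
  with_seed(seed, {
    val_idx <- integer(0)
    for (i in seq_along(pats)) {
      if (quota[i] == 0) next
      stratum <- which(pattern == pats[i])
      val_idx <- c(val_idx, stratum[sample.int(length(stratum), quota[i])])
    }
    list(train = records[setdiff(seq_along(records), val_idx)],
         validation = records[sort(val_idx)])
  })
}

#' Duplicate positive-labeled instances
#'
#' Every record carrying at least one positive label receives `factor`
#' extra copies (so it appears `1 + factor` times); all-negative records
#' appear once. The augmented set is then shuffled under `seed`.
#'
#' @param records list of labeled recordings (the training partition).
#' @param factor number of extra copies per positive instance.
#' @param seed shuffle seed (`NULL` keeps the expanded order).
#' @export
duplicate_positives <- function(records, factor = 2, seed = NULL) {
  if (factor < 0 || factor != round(factor)) stopf("`factor` must be a non-negative integer")
  idx <- duplicate_indices(label_matrix(records), factor)
  out <- records[idx]
  if (!is.null(seed)) out <- with_seed(seed, out[sample(length(out))])
  out
}

duplicate_indices <- function(y, factor) {
  any_pos <- rowSums(y) > 0
  rep(seq_len(nrow(y)), times = ifelse(any_pos, 1L + factor, 1L))
}

# --- flat parameter access for the optimizer --------------------------------

model_param_list <- function(model) {
  cp <- model$cell
  cell <- if (inherits(cp, "ltc_params")) {
    cp[c("theta_cm", "theta_gl", "x_leak", "theta_w", "gamma", "mu")]
  } else {
    cp[c("Wf", "bf", "Wg", "bg", "Wh", "bh")]
  }
  c(list(conv.Wx = model$conv$Wx, conv.Wh = model$conv$Wh, conv.b = model$conv$b,
         dense.W = model$dense$W, dense.b = model$dense$b),
    stats::setNames(cell, paste0("cell.", names(cell))))
}

set_model_params <- function(model, plist) {
  model$conv$Wx <- plist$conv.Wx; model$conv$Wh <- plist$conv.Wh; model$conv$b <- plist$conv.b
  model$dense$W <- plist$dense.W; model$dense$b <- plist$dense.b
  for (nm in grep("^cell\\.", names(plist), value = TRUE)) {
    model$cell[[sub("^cell\\.", "", nm)]] <- plist[[nm]]
  }
  model
}

grad_param_list <- function(gr) {
  c(list(conv.Wx = gr$conv$Wx, conv.Wh = gr$conv$Wh, conv.b = gr$conv$b,
         dense.W = gr$dense$W, dense.b = gr$dense$b),
    stats::setNames(gr$cell, paste0("cell.", names(gr$cell))))
}

adam_init <- function(plist) {
  list(m = lapply(plist, function(p) p * 0), v = lapply(plist, function(p) p * 0), t = 0L)
}

adam_update <- function(plist, glist, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(plist)) {
    g <- glist[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    plist[[nm]] <- plist[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = plist, state = state)
}

clip_global_norm <- function(glist, max_norm) {
  nrm <- sqrt(sum(vapply(glist, function(g) sum(g^2), numeric(1))))
  if (is.finite(nrm) && nrm > max_norm) glist <- lapply(glist, function(g) g * (max_norm / nrm))
  glist
}

# Preprocess raw records unless already a preprocessed dataset list.
as_model_input <- function(model, data) {
  if (is.list(data) && !is.null(data$x)) return(data)
  pp <- model$config$preprocess
  preprocess_dataset(data, filter = pp$filter, stft_cfg = pp$stft_cfg,
                     target_fs = pp$target_fs, target_len = pp$target_len)
}

#' Train a model
#'
#' Minimizes the mean binary cross-entropy over the six labels with Adam,
#' using hand-derived reverse-mode gradients through the ConvLSTM, dense
#' projection and continuous-time cell. Positive-instance duplication is
#' applied to the training partition only. The run is seeded end to end
#' (shuffling via `cfg$seed`; initialization in [build_model()]); training
#' aborts with a diagnostic if the loss turns non-finite.
#'
#' @param model an `ncp_model` from [build_model()].
#' @param train_data,val_data lists of labeled recordings, or preprocessed
#'   datasets from [preprocess_dataset()].
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (trained) and `log` (data.frame with one row
#'   per epoch: train/validation loss and per-label binary accuracy at
#'   threshold 0.5).
#' @export
train_model <- function(model, train_data, val_data, cfg = train_config(), verbose = FALSE) {
  if (!inherits(model, "ncp_model")) stopf("`model` must be an ncp_model")
  tr <- as_model_input(model, train_data)
  va <- as_model_input(model, val_data)
  if (is.null(tr$y) || is.null(va$y)) stopf("training requires labeled records")
  if (nrow(tr$y) == 0 || nrow(va$y) == 0) stopf("empty training or validation set")
  # fit the input standardization on the training partition only
  lx <- log1p(crop_freq_bins(model, tr$x))
  model$norm <- list(center = mean(lx), scale = max(stats::sd(lx), 1e-8))
  rm(lx)
  dup_idx <- duplicate_indices(tr$y, cfg$positive_duplication_factor)
  n_cls <- model$config$n_classes
  plist <- model_param_list(model)
  opt <- adam_init(plist)
  log_rows <- vector("list", cfg$epochs)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      order_idx <- dup_idx[sample(length(dup_idx))]
      ep_loss <- 0; ep_acc <- 0; ep_n <- 0
      for (start in seq(1, length(order_idx), by = cfg$batch_size)) {
        bidx <- order_idx[start:min(start + cfg$batch_size - 1, length(order_idx))]
        xb <- tr$x[bidx, , , , drop = FALSE]
        yb <- tr$y[bidx, , drop = FALSE]
        fwd <- forward_batch(model, xb, keep = TRUE)
        p <- pmin(pmax(fwd$scores, cfg$eps), 1 - cfg$eps)
        loss <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
        if (!is.finite(loss)) {
          stopf("training diverged at epoch %d (non-finite loss); lower the learning rate",
                epoch)
        }
        d_motor <- t(fwd$scores - yb) / (length(bidx) * n_cls)
        gr <- backward_batch(model, fwd, d_motor)
        glist <- clip_global_norm(grad_param_list(gr), cfg$clip_norm)
        upd <- adam_update(plist, glist, opt, cfg$learning_rate)
        plist <- upd$params; opt <- upd$state
        model <- set_model_params(model, plist)
        ep_loss <- ep_loss + loss * length(bidx)
        ep_acc <- ep_acc + sum((fwd$scores >= 0.5) == yb) / n_cls
        ep_n <- ep_n + length(bidx)
      }
      vp <- predict_scores(model, va$x)
      v_loss <- bce_loss(vp, va$y, cfg$eps)
      v_acc <- mean((vp >= 0.5) == va$y)
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, train_loss = ep_loss / ep_n, train_acc = ep_acc / ep_n,
        val_loss = v_loss, val_acc = v_acc)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f acc %.3f | val loss %.4f acc %.3f",
                        epoch, ep_loss / ep_n, ep_acc / ep_n, v_loss, v_acc))
      }
    }
  })
  list(model = model, log = do.call(rbind, log_rows))
}
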