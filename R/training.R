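#' Training configuration
#'
#' Defaults follow the study protocol: Adam, 60 epochs, at most 20 000
#' samples per class, a 15% validation split used for monitoring only
#' (never for model selection), and inverse-frequency class weighting.
#' Learning rate and batch sizes are standard defaults exposed here.
#'
#' @param epochs training epochs (final-epoch weights are kept; no early
#'   stopping).
#' @param per_class_cap maximum samples per class.
#' @param val_fraction fraction held out for monitoring.
#' @param learning_rate Adam learning rate.
#' @param batch_size mini-batch size.
#' @param seed RNG seed covering subsampling, validation split, shuffling
#'   and weight initialization.
#' @return a `training_config` list.
#' @export
training_config <- function(epochs = 60, per_class_cap = 20000,
                            val_fraction = 0.15, learning_rate = 1e-3,
                            batch_size = 128, seed = 1) {
  stopifnot(val_fraction > 0, val_fraction < 1, per_class_cap > 0, epochs > 0)
  structure(list(epochs = epochs, per_class_cap = per_class_cap,
                 val_fraction = val_fraction, learning_rate = learning_rate,
                 batch_size = batch_size, seed = seed),
            class = "training_config")
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (2 * n_c)`, normalized so the mean per-sample weight is 1 and
#' the total weighted sample mass equals `n_pos + n_neg`.
#'
#' @param n_pos,n_neg class counts (> 0).
#' @return named vector `c(w_pos, w_neg)`.
#' @export
class_weights <- function(n_pos, n_neg) {
  if (n_pos <= 0 || n_neg <= 0)
    stop("invalid input: both class counts must be positive")
  N <- n_pos + n_neg
  c(w_pos = N / (2 * n_pos), w_neg = N / (2 * n_neg))
}

#' Cap the number of samples per class
#'
#' Classes over the cap are randomly subsampled (reproducibly under the
#' seed); classes at or under the cap are untouched.
#'
#' @param labels binary 0/1 (or logical) label vector.
#' @param cap per-class maximum (default 20000).
#' @param seed RNG seed.
#' @return integer indices of the retained samples, in increasing order.
#' @export
subsample_per_class <- function(labels, cap = 20000, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  keep <- integer(0)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) > cap) idx <- sort(sample(idx, cap))
    keep <- c(keep, idx)
  }
  sort(keep)
}

# Shared epoch loop bookkeeping: weighted losses, shuffled mini-batches.
.epoch_batches <- function(n, batch_size) {
  ord <- sample(n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}

#' Train the base CNN
#'
#' Two-class training with weighted categorical cross-entropy and Adam.
#' PARTIAL-labelled tiles must not be in the pool: they are neither clean
#' positives nor clean negatives and are filtered here. A random 15% of the
#' training tiles is held out and its loss logged each epoch for monitoring.
#'
#' @param tiles 36 x 21 x n array of dB tiles.
#' @param labels per-tile labels (`"POSITIVE"`/`"NEGATIVE"`/`"PARTIAL"`).
#' @param cfg a [training_config()].
#' @param arch a [cnn_arch_spec()].
#' @param verbose print per-epoch losses.
#' @return a `base_cnn` model with an additional `history` field
#'   (data frame of per-epoch train/validation losses).
#' @export
train_base_cnn <- function(tiles, labels, cfg = training_config(),
                           arch = cnn_arch_spec(), verbose = FALSE) {
  keep <- labels != "PARTIAL"
  tiles <- tiles[, , keep, drop = FALSE]
  y <- as.integer(labels[keep] == "POSITIVE")
  sel <- subsample_per_class(y, cfg$per_class_cap, seed = cfg$seed)
  tiles <- tiles[, , sel, drop = FALSE]
  y <- y[sel]
  if (length(unique(y)) < 2)
    stop("invalid input: need both classes after filtering")

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  n <- length(y)
  n_val <- round(cfg$val_fraction * n)
  val_idx <- sample(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  w <- class_weights(sum(y[tr_idx] == 1), sum(y[tr_idx] == 0))
  model <- build_base_cnn(arch, seed = cfg$seed)
  st <- adam_init(model$params)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))

  wce <- function(probs, yy) {
    ww <- ifelse(yy == 1, w["w_pos"], w["w_neg"])
    p <- pmax(probs[cbind(seq_along(yy), yy + 1)], 1e-12)
    mean(ww * -log(p))
  }
  for (ep in seq_len(cfg$epochs)) {
    batches <- .epoch_batches(length(tr_idx), cfg$batch_size)
    tl <- 0; tn <- 0
    for (bi in batches) {
      idx <- tr_idx[bi]
      out <- cnn_forward_batch(model, tiles[, , idx, drop = FALSE],
                               training = TRUE, keep_cache = TRUE)
      model$running <- out$running
      yy <- y[idx]
      B <- length(idx)
      Y <- matrix(0, B, 2); Y[cbind(seq_len(B), yy + 1)] <- 1
      ww <- ifelse(yy == 1, w["w_pos"], w["w_neg"])
      dZ <- (out$probs - Y) * ww / B
      grads <- cnn_backward_batch(model, out$cache, dZ)
      upd <- adam_step(model$params, grads, st, lr = cfg$learning_rate)
      model$params <- upd$params
      st <- upd$state
      tl <- tl + wce(out$probs, yy) * B; tn <- tn + B
    }
    vout <- cnn_forward_batch(model, tiles[, , val_idx, drop = FALSE],
                              training = FALSE)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl / tn,
                                   val_loss = wce(vout$probs, y[val_idx])))
    if (verbose)
      message(sprintf("cnn epoch %d  train %.4f  val %.4f", ep,
                      tl / tn, hist$val_loss[ep]))
  }
  # Recalibrate batch-norm running statistics under the final weights:
  # a cumulative-mean pass over training batches (momentum 1/i), so
  # inference-mode statistics do not lag the last weight updates.
  calib <- .epoch_batches(length(tr_idx), cfg$batch_size)
  for (i in seq_along(calib)) {
    out <- cnn_forward_batch(model, tiles[, , tr_idx[calib[[i]]], drop = FALSE],
                             training = TRUE, bn_momentum = 1 / i)
    model$running <- out$running
  }
  vout <- cnn_forward_batch(model, tiles[, , val_idx, drop = FALSE],
                            training = FALSE)
  hist$val_loss_calibrated <- c(rep(NA_real_, nrow(hist) - 1),
                                wce(vout$probs, y[val_idx]))
  model$history <- hist
  model
}

#' Train a hybrid LSTM head on cached CNN outputs
#'
#' Optimizes only the LSTM-head parameters (the paired CNN stays frozen)
#' with weighted binary cross-entropy and Adam. If the head carries a CNN
#' fingerprint it must match `cache_fingerprint`.
#'
#' @param sequences output of [assemble_sequences()] (training windows, i.e.
#'   PARTIAL prediction points already excluded), or a list of such outputs
#'   from several recordings.
#' @param cfg a [training_config()].
#' @param head a [build_hybrid_head()]; built fresh when `NULL`.
#' @param hybrid_cfg a [hybrid_config()], required when `head` is NULL.
#' @param cache_fingerprint fingerprint of the CNN that produced the cached
#'   sequences, checked against the head's stored fingerprint.
#' @param verbose print per-epoch losses.
#' @return the trained `hybrid_head` with a `history` field.
#' @export
train_hybrid <- function(sequences, cfg = training_config(batch_size = 32),
                         head = NULL, hybrid_cfg = NULL,
                         cache_fingerprint = NULL, verbose = FALSE) {
  if (!is.null(sequences$inputs)) sequences <- list(sequences)
  X <- do.call(.abind1, lapply(sequences, `[[`, "inputs"))
  y <- unlist(lapply(sequences, `[[`, "labels"))
  if (anyNA(y)) stop("invalid input: training sequences must not have PARTIAL prediction points")
  if (is.null(head)) {
    if (is.null(hybrid_cfg)) stop("need head or hybrid_cfg")
    head <- build_hybrid_head(hybrid_cfg, seed = cfg$seed,
                              cnn_fingerprint = cache_fingerprint)
  }
  if (!is.null(head$cnn_fingerprint) && !is.null(cache_fingerprint) &&
      !identical(head$cnn_fingerprint, cache_fingerprint))
    stop("configuration error: cache fingerprint does not match the head's paired CNN")

  sel <- subsample_per_class(y, cfg$per_class_cap, seed = cfg$seed)
  X <- X[sel, , , drop = FALSE]; y <- y[sel]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1)
  n <- length(y)
  n_val <- round(cfg$val_fraction * n)
  val_idx <- sample(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  w <- class_weights(max(sum(y[tr_idx] == 1), 1), max(sum(y[tr_idx] == 0), 1))
  st <- adam_init(head$params)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  bce <- function(p, yy) {
    ww <- ifelse(yy == 1, w["w_pos"], w["w_neg"])
    mean(ww * -(yy * log(pmax(p, 1e-12)) + (1 - yy) * log(pmax(1 - p, 1e-12))))
  }
  for (ep in seq_len(cfg$epochs)) {
    batches <- .epoch_batches(length(tr_idx), cfg$batch_size)
    tl <- 0; tn <- 0
    for (bi in batches) {
      idx <- tr_idx[bi]
      out <- hybrid_forward_batch(head, X[idx, , , drop = FALSE], keep_cache = TRUE)
      yy <- y[idx]
      ww <- ifelse(yy == 1, w["w_pos"], w["w_neg"])
      dlogit <- (out$prob - yy) * ww / length(idx)
      grads <- hybrid_backward_batch(head, out$cache, dlogit)
      upd <- adam_step(head$params, grads, st, lr = cfg$learning_rate)
      head$params <- upd$params
      st <- upd$state
      tl <- tl + bce(out$prob, yy) * length(idx); tn <- tn + length(idx)
    }
    vp <- hybrid_forward_batch(head, X[val_idx, , , drop = FALSE])$prob
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl / tn,
                                   val_loss = bce(vp, y[val_idx])))
    if (verbose)
      message(sprintf("hybrid %s epoch %d  train %.4f  val %.4f",
                      head$cfg$variant, ep, tl / tn, hist$val_loss[ep]))
  }
  head$history <- hist
  head
}

# bind sequence arrays along the first (sample) dimension
.abind1 <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) dim(p)[1] > 0, logical(1))]
  if (length(parts) == 0) stop("no sequences to train on")
  d <- dim(parts[[1]])
  ntot <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  out <- array(NA_real_, c(ntot, d[2], d[3]))
  off <- 0
  for (p in parts) {
    out[off + seq_len(dim(p)[1]), , ] <- p
    off <- off + dim(p)[1]
  }
  out
}

#' Enumerate the experiment grid
#'
#' Cartesian product of hybrid variants, prediction-point settings and folds
#' in deterministic order; per-fold CNN runs are deduplicated since one base
#' CNN serves all hybrid configurations of its fold. The full study grid
#' (3 variants x 4 PP settings x 10 folds) yields 120 hybrid runs and 10 CNN
#' runs.
#'
#' @param variants character vector of hybrid variants.
#' @param pp_fractions numeric vector of PP settings.
#' @param folds integer vector of fold indices.
#' @param time_steps sequence length for all runs.
#' @return list with `hybrid_runs` (data frame: variant, pp_fraction, fold,
#'   time_steps) and `cnn_runs` (data frame: fold).
#' @export
enumerate_experiments <- function(variants = c("SCORE", "FEATURE", "SCORE_PLUS_FEATURE"),
                                  pp_fractions = c(0.50, 0.67, 0.75, 1.00),
                                  folds = 1:10, time_steps = 108) {
  stopifnot(length(variants) > 0, length(pp_fractions) > 0, length(folds) > 0)
  hybrid_runs <- expand.grid(variant = variants, pp_fraction = pp_fractions,
                             fold = folds, KEEP.OUT.ATTRS = FALSE,
                             stringsAsFactors = FALSE)
  hybrid_runs$time_steps <- time_steps
  list(hybrid_runs = hybrid_runs, cnn_runs = data.frame(fold = unique(folds)))
}
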