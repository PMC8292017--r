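#' Hybrid detector configuration
#'
#' @param variant one of `"SCORE"` (the CNN's scalar score, input width 1),
#'   `"FEATURE"` (the 32-d embedding) or `"SCORE_PLUS_FEATURE"` (embedding
#'   with the score appended, width 33).
#' @param time_steps sequence length T (108 at the default 1 s hop; 88 in the
#'   1.25 s hop granularity experiment).
#' @param pp_fraction prediction-point position as a fraction of T; one of
#'   0.50, 0.67, 0.75, 1.00 in the study grid (any value in (0, 1] accepted).
#' @param lstm_units widths of the two LSTM layers.
#' @param embedding_dim CNN embedding width.
#' @return a `hybrid_config` list with derived field `input_dim`.
#' @export
hybrid_config <- function(variant = c("SCORE", "FEATURE", "SCORE_PLUS_FEATURE"),
                          time_steps = 108, pp_fraction = 1.0,
                          lstm_units = c(32, 16), embedding_dim = 32) {
  variant <- match.arg(variant)
  if (time_steps < 2) stop("invalid input: time_steps must be >= 2")
  if (pp_fraction <= 0 || pp_fraction > 1)
    stop("invalid input: pp_fraction must be in (0, 1]")
  D <- switch(variant, SCORE = 1L, FEATURE = embedding_dim,
              SCORE_PLUS_FEATURE = embedding_dim + 1L)
  structure(list(variant = variant, time_steps = as.integer(time_steps),
                 pp_fraction = pp_fraction, lstm_units = lstm_units,
                 embedding_dim = embedding_dim, input_dim = D),
            class = "hybrid_config")
}

#' Prediction-point index within a sequence
#'
#' 1-based position `round(pp_fraction * T)` (ties rounded up), clamped to
#' `[1, T]`. At 1.0 the PP sits at the sequence end (no future context); at
#' 0.5 past and future context are balanced.
#'
#' @param time_steps sequence length T (>= 2).
#' @param pp_fraction fraction in (0, 1].
#' @return integer position.
#' @export
pp_index <- function(time_steps, pp_fraction) {
  if (time_steps < 2) stop("invalid input: time_steps must be >= 2")
  if (pp_fraction <= 0 || pp_fraction > 1)
    stop("invalid input: pp_fraction must be in (0, 1]")
  max(1L, min(as.integer(time_steps), as.integer(floor(pp_fraction * time_steps + 0.5))))
}

#' Assemble fixed-length sequences of cached CNN outputs
#'
#' Slides a window of `time_steps` consecutive grid segments over one
#' recording's output cache. Each admissible window yields one sample whose
#' label is the binary label of the prediction-point segment. Windows whose
#' PP segment is PARTIAL are excluded from training sets (mirroring the CNN
#' exclusion rule) but PARTIAL segments remain inside window bodies.
#'
#' @param cache a [precompute_outputs()] result for one recording.
#' @param labels per-segment labels from [label_segments()].
#' @param cfg a [hybrid_config()].
#' @param keep_partial_pp if `TRUE`, windows with PARTIAL prediction points
#'   are kept (with label `NA`); used at inference/evaluation time.
#' @return list with `inputs` (n_seq x D x T array), `labels` (0/1 or NA),
#'   `pp_segment` (grid index of each PP segment) and `pp_position`
#'   (PP index within the window). A recording shorter than T segments
#'   yields zero samples with a warning.
#' @export
assemble_sequences <- function(cache, labels, cfg, keep_partial_pp = FALSE) {
  T <- cfg$time_steps
  n <- cache$n
  stopifnot(length(labels) == n)
  if (n < T) {
    warning("recording shorter than ", T, " segments; no sequences")
    return(list(inputs = array(0, c(0, cfg$input_dim, T)), labels = numeric(0),
                pp_segment = integer(0), pp_position = pp_index(T, cfg$pp_fraction)))
  }
  p <- pp_index(T, cfg$pp_fraction)
  n_win <- n - T + 1
  feat <- switch(cfg$variant,
    SCORE = matrix(cache$scores, ncol = 1),
    FEATURE = cache$embeddings,
    SCORE_PLUS_FEATURE = cbind(cache$embeddings, cache$scores))
  D <- ncol(feat)
  inputs <- array(NA_real_, c(n_win, D, T))
  for (t in seq_len(T))
    inputs[, , t] <- feat[t:(t + n_win - 1), , drop = FALSE]
  pp_segment <- seq_len(n_win) + p - 1
  lab_state <- labels[pp_segment]
  y <- ifelse(lab_state == "POSITIVE", 1, ifelse(lab_state == "NEGATIVE", 0, NA))
  if (!keep_partial_pp) {
    keep <- !is.na(y)
    inputs <- inputs[keep, , , drop = FALSE]
    y <- y[keep]
    pp_segment <- pp_segment[keep]
  }
  list(inputs = inputs, labels = y, pp_segment = pp_segment, pp_position = p)
}

#' Build (initialize) an LSTM hybrid head
#'
#' Two LSTM layers (32 and 16 units) followed by a single-unit dense layer
#' with sigmoid activation. The recurrence consumes all T steps of a window;
#' the detection score is read after the final step and the label is attached
#' to the prediction-point segment, so windows with pp_fraction < 1 expose
#' future context to the recurrence before the score is emitted.
#'
#' @param cfg a [hybrid_config()].
#' @param seed RNG seed for weight initialization.
#' @param cnn_fingerprint optional fingerprint (e.g. from
#'   [cnn_fingerprint()]) of the paired frozen CNN, stored for cache
#'   validation.
#' @return an object of class `hybrid_head` with fields `cfg`, `params` and
#'   `cnn_fingerprint`.
#' @export
build_hybrid_head <- function(cfg, seed = 1, cnn_fingerprint = NULL) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  D <- cfg$input_dim
  H1 <- cfg$lstm_units[1]; H2 <- cfg$lstm_units[2]
  params <- list(
    W1 = .init_mat(D + H1, 4 * H1, D + H1),
    b1 = rep(0, 4 * H1),
    W2 = .init_mat(H1 + H2, 4 * H2, H1 + H2),
    b2 = rep(0, 4 * H2),
    Wo = .init_mat(H2, 1, H2),
    bo = 0)
  params$b1[(H1 + 1):(2 * H1)] <- 1    # forget-gate bias
  params$b2[(H2 + 1):(2 * H2)] <- 1
  structure(list(cfg = cfg, params = params, cnn_fingerprint = cnn_fingerprint),
            class = "hybrid_head")
}

#' Fingerprint of a CNN's weights
#'
#' A short digest used to verify that a hybrid head is paired with the CNN
#' whose outputs produced its training cache.
#'
#' @param model a [build_base_cnn()] result.
#' @return a character scalar.
#' @export
cnn_fingerprint <- function(model) {
  v <- unlist(model$params, use.names = FALSE)
  sprintf("%d-%.12e-%.12e", length(v), sum(v), sum(v * seq_along(v) %% 97))
}

# One LSTM layer forward over all T steps. X: (N, D, T). Gate order i,f,g,o.
.lstm_layer_fwd <- function(X, W, b, Hn, keep_cache = FALSE) {
  N <- dim(X)[1]; T <- dim(X)[3]
  h <- matrix(0, N, Hn); cc <- matrix(0, N, Hn)
  Hseq <- array(NA_real_, c(N, Hn, T))
  steps <- if (keep_cache) vector("list", T) else NULL
  for (t in seq_len(T)) {
    xt <- X[, , t, drop = FALSE]; dim(xt) <- c(N, dim(X)[2])
    Z <- cbind(xt, h) %*% W
    Z <- Z + rep(b, each = N)
    i_g <- sigmoid(Z[, 1:Hn, drop = FALSE])
    f_g <- sigmoid(Z[, (Hn + 1):(2 * Hn), drop = FALSE])
    g_g <- tanh(Z[, (2 * Hn + 1):(3 * Hn), drop = FALSE])
    o_g <- sigmoid(Z[, (3 * Hn + 1):(4 * Hn), drop = FALSE])
    c_prev <- cc
    cc <- f_g * c_prev + i_g * g_g
    tc <- tanh(cc)
    if (keep_cache)
      steps[[t]] <- list(inp = cbind(xt, h),
                         i = i_g, f = f_g, g = g_g, o = o_g,
                         c_prev = c_prev, c = cc, tc = tc)
    h <- o_g * tc
    Hseq[, , t] <- h
  }
  list(Hseq = Hseq, h_last = h, steps = steps)
}

.lstm_layer_bwd <- function(steps, W, Hn, Din, dHseq, N, T) {
  dW <- matrix(0, nrow(W), ncol(W)); db <- rep(0, ncol(W))
  dX <- array(0, c(N, Din, T))
  dh_next <- matrix(0, N, Hn); dc_next <- matrix(0, N, Hn)
  for (t in T:1) {
    st <- steps[[t]]
    dh <- dHseq[, , t, drop = FALSE]; dim(dh) <- c(N, Hn)
    dh <- dh + dh_next
    do_g <- dh * st$tc
    dc <- dh * st$o * (1 - st$tc^2) + dc_next
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dc_next <- dc * st$f
    dZ <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_g * st$o * (1 - st$o))
    dW <- dW + crossprod(st$inp, dZ)
    db <- db + colSums(dZ)
    dInp <- dZ %*% t(W)
    dX[, , t] <- dInp[, 1:Din, drop = FALSE]
    dh_next <- dInp[, (Din + 1):(Din + Hn), drop = FALSE]
  }
  list(dW = dW, db = db, dX = dX)
}

# Full head forward: X (N, D, T) -> probabilities (N).
hybrid_forward_batch <- function(head, X, keep_cache = FALSE) {
  p <- head$params
  H1 <- head$cfg$lstm_units[1]; H2 <- head$cfg$lstm_units[2]
  l1 <- .lstm_layer_fwd(X, p$W1, p$b1, H1, keep_cache)
  l2 <- .lstm_layer_fwd(l1$Hseq, p$W2, p$b2, H2, keep_cache)
  logit <- drop(l2$h_last %*% p$Wo) + p$bo
  prob <- sigmoid(logit)
  out <- list(prob = prob, logit = logit)
  if (keep_cache) out$cache <- list(l1 = l1, l2 = l2, X = X)
  out
}

hybrid_backward_batch <- function(head, cache, dlogit) {
  p <- head$params
  cfg <- head$cfg
  H1 <- cfg$lstm_units[1]; H2 <- cfg$lstm_units[2]
  N <- dim(cache$X)[1]; T <- dim(cache$X)[3]
  dWo <- crossprod(cache$l2$h_last, matrix(dlogit, ncol = 1))
  dbo <- sum(dlogit)
  dH2 <- array(0, c(N, H2, T))
  dH2[, , T] <- matrix(dlogit, N, H2) * matrix(p$Wo, N, H2, byrow = TRUE)
  b2 <- .lstm_layer_bwd(cache$l2$steps, p$W2, H2, H1, dH2, N, T)
  b1 <- .lstm_layer_bwd(cache$l1$steps, p$W1, H1, cfg$input_dim, b2$dX, N, T)
  list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db, Wo = dWo, bo = dbo)
}

#' Score one assembled sequence with a hybrid head
#'
#' @param head a [build_hybrid_head()] (trained or not).
#' @param inputs one D x T matrix, or the `inputs` array from
#'   [assemble_sequences()].
#' @return numeric vector of detection scores in \[0, 1\]; deterministic in
#'   inference.
#' @export
hybrid_score <- function(head, inputs) {
  if (is.matrix(inputs)) {
    X <- array(inputs, c(1, dim(inputs)))
  } else X <- inputs
  hybrid_forward_batch(head, X)$prob
}

#' Stream detection over a whole recording
#'
#' Runs the full two-stage pipeline on a continuous recording: tiles on the
#' segment grid, frozen-CNN outputs, sliding windows of `cfg$time_steps`
#' cached outputs, and one hybrid score per admissible prediction-point
#' position. Leading/trailing segments without full context carry `NA`.
#'
#' @param cnn_model frozen [build_base_cnn()].
#' @param hybrid_model [build_hybrid_head()] paired with `cnn_model`.
#' @param recording a [waveform_recording()] at the working rate.
#' @param hop_s grid hop (s).
#' @param cache optional precomputed [precompute_outputs()] for the recording.
#' @return data frame with columns `source_id`, `segment_start_s`, `score`
#'   (NA where no full window covers the segment) and `cnn_score`.
#' @export
detect_stream <- function(cnn_model, hybrid_model, recording, hop_s = 1,
                          cache = NULL) {
  cfg <- hybrid_model$cfg
  ext <- extract_tiles(recording, hop_s = hop_s)
  n <- ext$grid$n_segments
  if (n < cfg$time_steps) {
    warning("recording shorter than ", cfg$time_steps, " segments; no detections")
    return(data.frame(source_id = character(0), segment_start_s = numeric(0),
                      score = numeric(0), cnn_score = numeric(0)))
  }
  if (is.null(cache)) cache <- precompute_outputs(cnn_model, ext$tiles)
  seqs <- assemble_sequences(cache, rep("NEGATIVE", n), cfg, keep_partial_pp = TRUE)
  probs <- hybrid_forward_batch(hybrid_model, seqs$inputs)$prob
  score <- rep(NA_real_, n)
  score[seqs$pp_segment] <- probs
  data.frame(source_id = recording$source_id,
             segment_start_s = ext$grid$start_times_s,
             score = score, cnn_score = cache$scores)
}
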