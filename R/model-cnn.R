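#' One-dimensional Laplacian-of-Gaussian kernel
#'
#' Samples the negated second derivative of a Gaussian at integer offsets,
#' truncated at +/- ceil(4 sigma), then subtracts the mean so the taps sum to
#' exactly zero. The sign convention makes a ridge (a local maximum along
#' frequency, such as a note's energy band) produce a positive center
#' response.
#'
#' @param sigma kernel scale in frequency bins (> 0); the detector uses
#'   scales 2 and 4.
#' @return an object of class `log_kernel` with fields `sigma` and `taps`
#'   (odd length, symmetric, zero sum).
#' @export
make_log_kernel <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("invalid input: sigma must be a positive scalar")
  r <- ceiling(4 * sigma)
  x <- (-r):r
  g2 <- (x^2 / sigma^2 - 1) / (sigma^3 * sqrt(2 * pi)) * exp(-x^2 / (2 * sigma^2))
  taps <- -g2        # negate: ridge -> positive center response
  taps <- taps - mean(taps)
  structure(list(sigma = sigma, taps = taps), class = "log_kernel")
}

#' Apply a LoG kernel along the frequency axis of a tile
#'
#' One-dimensional convolution applied independently to each time column,
#' with edge-replication padding so the output has the tile's shape.
#'
#' @param tile a `spectrogram_tile` or bare matrix (frequency x time).
#' @param kernel a [make_log_kernel()] result.
#' @return filtered matrix of the same shape.
#' @export
apply_log_filter <- function(tile, kernel) {
  vals <- if (inherits(tile, "spectrogram_tile")) tile$values else tile
  H <- nrow(vals)
  if (length(kernel$taps) > 2 * H - 1)
    stop("invalid input: kernel longer than 2*", H, "-1 taps")
  L <- .log_matrix(kernel$taps, H)
  L %*% vals
}

# Dense H x H operator realizing the 1-D convolution with replicate padding.
.log_matrix <- function(taps, H) {
  r <- (length(taps) - 1) / 2
  L <- matrix(0, H, H)
  for (i in seq_len(H)) {
    idx <- pmin(pmax(i + (-r):r, 1), H)   # replicate edges
    for (k in seq_along(taps)) L[i, idx[k]] <- L[i, idx[k]] + taps[k]
  }
  L
}

#' Architecture description of the base CNN
#'
#' Pins the detector geometry: fixed LoG pre-conditioning at two scales each
#' followed by twelve trainable 3x3 convolutions (26 channels total), four
#' quasi-dense blocks of sizes (2, 2, 2, 1) with growth rate 12 and
#' compressing transition layers, global average pooling, a 32-unit embedding
#' layer (FCN-1), a 16-unit FCN-2 and a 2-way softmax.
#'
#' @param log_sigmas LoG scales (frequency bins).
#' @param convs_per_scale trainable 3x3 convolutions per LoG scale.
#' @param block_sizes composite layers per quasi-dense block.
#' @param growth_rate channels added per composite layer.
#' @param embedding_dim FCN-1 width (the feature embedding fed to hybrids).
#' @param fcn2_dim FCN-2 width.
#' @param n_classes output classes.
#' @param transition_compression channel compression of transition layers.
#' @param input_shape tile shape (frequency bins, time frames).
#' @return a `cnn_arch_spec` list.
#' @export
cnn_arch_spec <- function(log_sigmas = c(2, 4), convs_per_scale = 12,
                          block_sizes = c(2, 2, 2, 1), growth_rate = 12,
                          embedding_dim = 32, fcn2_dim = 16, n_classes = 2,
                          transition_compression = 0.5,
                          input_shape = c(36, 21)) {
  spec <- list(log_sigmas = log_sigmas, convs_per_scale = convs_per_scale,
               block_sizes = block_sizes, growth_rate = growth_rate,
               embedding_dim = embedding_dim, fcn2_dim = fcn2_dim,
               n_classes = n_classes,
               transition_compression = transition_compression,
               input_shape = input_shape)
  stopifnot(all(unlist(spec[c("convs_per_scale", "block_sizes", "growth_rate",
                              "embedding_dim", "fcn2_dim", "n_classes")]) > 0))
  structure(spec, class = "cnn_arch_spec")
}

#' Pre-conditioning output channel count
#' @param spec a [cnn_arch_spec()].
#' @return number of channels emitted by the pre-conditioning layer
#'   (n_scales + n_scales * convs_per_scale; 26 at defaults).
#' @export
precond_channels <- function(spec = cnn_arch_spec()) {
  s <- length(spec$log_sigmas)
  s + s * spec$convs_per_scale
}

#' Channel bookkeeping through the quasi-dense subnetwork
#'
#' Traces the channel count from the pre-conditioning output through every
#' quasi-dense block (a block with input C and size L emits C + L * growth
#' channels) and transition layer.
#'
#' @param spec a [cnn_arch_spec()].
#' @return data frame with one row per block: `block`, `input_channels`,
#'   `output_channels`.
#' @export
cnn_channel_counts <- function(spec = cnn_arch_spec()) {
  tr <- .channel_trace(spec)
  data.frame(block = seq_along(tr$blocks),
             input_channels = vapply(tr$blocks, `[[`, numeric(1), "input"),
             output_channels = vapply(tr$blocks, `[[`, numeric(1), "output"))
}

# Channel trace through the quasi-dense subnetwork: input C, each block adds
# L * growth channels, each transition compresses by the stated factor.
.channel_trace <- function(spec) {
  C <- precond_channels(spec)
  blocks <- list()
  nb <- length(spec$block_sizes)
  for (i in seq_len(nb)) {
    Lb <- spec$block_sizes[i]
    out <- C + Lb * spec$growth_rate
    blocks[[i]] <- c(input = C, output = out)
    C <- out
    if (i < nb) C <- floor(C * spec$transition_compression)
  }
  list(blocks = blocks, final = C)
}

#' Build (initialize) the base CNN
#'
#' Creates the model with fixed (non-trainable) LoG operators and seeded
#' He-style initialization of all trainable weights. The quasi-dense rule:
#' the first composite layer of a block consumes the block input; every later
#' composite layer consumes only the preceding layer's output; the block
#' output concatenates the block input with all layer outputs (so a block
#' with input C and size L emits C + L * growth channels).
#'
#' @param spec a [cnn_arch_spec()].
#' @param seed RNG seed for weight initialization.
#' @return an object of class `base_cnn` with fields `spec`, `log_kernels`,
#'   `log_mats` (fixed operators), `params` (trainable arrays), `running`
#'   (batch-norm running statistics) and `init_seed`.
#' @export
build_base_cnn <- function(spec = cnn_arch_spec(), seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  H <- spec$input_shape[1]
  kernels <- lapply(spec$log_sigmas, make_log_kernel)
  log_mats <- lapply(kernels, function(k) .log_matrix(k$taps, H))

  params <- list()
  running <- list()
  g <- spec$growth_rate
  conv3 <- function(cin, cout) .init_mat(9 * cin, cout, 9 * cin)
  add_bn <- function(nm, C) {
    params[[paste0(nm, "_gamma")]] <<- rep(1, C)
    params[[paste0(nm, "_beta")]] <<- rep(0, C)
    running[[paste0(nm, "_mean")]] <<- rep(0, C)
    running[[paste0(nm, "_var")]] <<- rep(1, C)
  }
  for (s in seq_along(spec$log_sigmas)) {
    params[[paste0("pre", s, "_K")]] <- conv3(1, spec$convs_per_scale)
    params[[paste0("pre", s, "_b")]] <- rep(0, spec$convs_per_scale)
  }
  tr <- .channel_trace(spec)
  for (i in seq_along(spec$block_sizes)) {
    Cin <- tr$blocks[[i]]["input"]
    for (l in seq_len(spec$block_sizes[i])) {
      cl_in <- if (l == 1) Cin else g     # quasi-dense: later layers see only y_{l-1}
      nm <- paste0("b", i, "l", l)
      add_bn(nm, cl_in)
      params[[paste0(nm, "_K")]] <- conv3(cl_in, g)
      params[[paste0(nm, "_b")]] <- rep(0, g)
    }
    if (i < length(spec$block_sizes)) {
      Cout_blk <- tr$blocks[[i]]["output"]
      Ct <- floor(Cout_blk * spec$transition_compression)
      nm <- paste0("t", i)
      add_bn(nm, Cout_blk)
      params[[paste0(nm, "_K")]] <- .init_mat(Cout_blk, Ct, Cout_blk)
      params[[paste0(nm, "_b")]] <- rep(0, Ct)
    }
  }
  add_bn("fin", tr$final)
  params$fc1_W <- .init_mat(tr$final, spec$embedding_dim, tr$final)
  params$fc1_b <- rep(0, spec$embedding_dim)
  params$fc2_W <- .init_mat(spec$embedding_dim, spec$fcn2_dim, spec$embedding_dim)
  params$fc2_b <- rep(0, spec$fcn2_dim)
  params$clf_W <- .init_mat(spec$fcn2_dim, spec$n_classes, spec$fcn2_dim)
  params$clf_b <- rep(0, spec$n_classes)

  structure(list(spec = spec, log_kernels = kernels, log_mats = log_mats,
                 params = params, running = running, init_seed = seed),
            class = "base_cnn")
}

#' Count trainable parameters of a CNN
#' @param model a [build_base_cnn()] result.
#' @return integer count (LoG taps are fixed and excluded).
#' @export
count_cnn_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Trainable parameter count under full dense-block connectivity
#'
#' Counts the parameters the same architecture would need if every composite
#' layer inside a block received the concatenation of the block input and all
#' preceding layer outputs (classical DenseNet wiring); used to verify that
#' the quasi-dense rule is strictly smaller.
#'
#' @param spec a [cnn_arch_spec()].
#' @param quasi if `TRUE`, count the quasi-dense wiring instead.
#' @return integer parameter count.
#' @export
count_dense_variant_params <- function(spec = cnn_arch_spec(), quasi = FALSE) {
  g <- spec$growth_rate
  n <- 0
  n <- n + length(spec$log_sigmas) * (9 * spec$convs_per_scale + spec$convs_per_scale)
  tr <- .channel_trace(spec)
  for (i in seq_along(spec$block_sizes)) {
    Cin <- tr$blocks[[i]]["input"]
    for (l in seq_len(spec$block_sizes[i])) {
      cl_in <- if (quasi) { if (l == 1) Cin else g } else Cin + (l - 1) * g
      n <- n + 2 * cl_in + 9 * cl_in * g + g
    }
    if (i < length(spec$block_sizes)) {
      Cout_blk <- tr$blocks[[i]]["output"]
      Ct <- floor(Cout_blk * spec$transition_compression)
      n <- n + 2 * Cout_blk + Cout_blk * Ct + Ct
    }
  }
  n <- n + 2 * tr$final
  n <- n + tr$final * spec$embedding_dim + spec$embedding_dim
  n <- n + spec$embedding_dim * spec$fcn2_dim + spec$fcn2_dim
  n <- n + spec$fcn2_dim * spec$n_classes + spec$n_classes
  unname(n)
}

# ---- forward / backward ----------------------------------------------------

# tiles: array (36, 21, N) of dB values in [-120, 0]; mapped to [0, 1] here.
cnn_forward_batch <- function(model, tiles, training = FALSE,
                              keep_cache = FALSE, bn_momentum = 0.1) {
  spec <- model$spec
  H <- spec$input_shape[1]; W <- spec$input_shape[2]
  if (length(dim(tiles)) == 2) dim(tiles) <- c(dim(tiles), 1)
  if (dim(tiles)[1] != H || dim(tiles)[2] != W)
    stop("invalid input: tiles must be ", H, " x ", W)
  N <- dim(tiles)[3]
  p <- model$params; run <- model$running
  g <- spec$growth_rate
  x01 <- 1 + pmax(tiles, -120) / 120
  X36 <- matrix(x01, nrow = H)            # H x (W*N) columns (w, n)

  # pre-conditioning: fixed LoG responses + trainable convs per scale
  chans <- list()
  pre_caches <- list()
  for (s in seq_along(model$log_mats)) {
    resp <- matrix(model$log_mats[[s]] %*% X36, nrow = 1)   # 1 x (HWN)
    chans[[length(chans) + 1]] <- resp
    cv <- conv3_fwd(resp, H, W, N, p[[paste0("pre", s, "_K")]],
                    p[[paste0("pre", s, "_b")]])
    pre_caches[[s]] <- cv$cache
    chans[[length(chans) + 1]] <- cv$out
  }
  # channel order: [LoG_1, conv(LoG_1), LoG_2, conv(LoG_2), ...]
  M <- do.call(rbind, chans)

  bn_caches <- list(); conv_caches <- list()
  pool_caches <- list(); block_meta <- list()
  curH <- H; curW <- W
  composite <- function(nm, Min) {
    bn <- bn_relu_fwd(Min, p[[paste0(nm, "_gamma")]], p[[paste0(nm, "_beta")]],
                      run[[paste0(nm, "_mean")]], run[[paste0(nm, "_var")]],
                      training, momentum = bn_momentum)
    run[[paste0(nm, "_mean")]] <<- bn$run_mean
    run[[paste0(nm, "_var")]] <<- bn$run_var
    bn_caches[[nm]] <<- bn$cache
    bn$out
  }
  for (i in seq_along(spec$block_sizes)) {
    Lb <- spec$block_sizes[i]
    ylist <- list(M)
    for (l in seq_len(Lb)) {
      nm <- paste0("b", i, "l", l)
      Min <- ylist[[l]]                   # block input for l=1, y_{l-1} after
      a <- composite(nm, Min)
      cv <- conv3_fwd(a, curH, curW, N, p[[paste0(nm, "_K")]], p[[paste0(nm, "_b")]])
      conv_caches[[nm]] <- cv$cache
      ylist[[l + 1]] <- cv$out
    }
    M <- do.call(rbind, ylist)            # concat(input, y_1..y_L)
    block_meta[[i]] <- list(widths = vapply(ylist, nrow, integer(1)))
    if (i < length(spec$block_sizes)) {
      nm <- paste0("t", i)
      a <- composite(nm, M)
      cv <- conv1_fwd(a, p[[paste0(nm, "_K")]], p[[paste0(nm, "_b")]])
      conv_caches[[nm]] <- cv$cache
      pl <- pool2_fwd(cv$out, curH, curW, N)
      pool_caches[[nm]] <- pl$cache
      M <- pl$out
      curH <- curH %/% 2; curW <- curW %/% 2
    }
  }
  a <- composite("fin", M)
  gp <- gap_fwd(a, curH, curW, N)
  f1 <- dense_fwd(gp$out, p$fc1_W, p$fc1_b)
  e1 <- relu_fwd(f1$out)
  emb <- e1$out                           # the 32-d feature embedding
  f2 <- dense_fwd(emb, p$fc2_W, p$fc2_b)
  e2 <- relu_fwd(f2$out)
  fz <- dense_fwd(e2$out, p$clf_W, p$clf_b)
  probs <- softmax_rows(fz$out)

  out <- list(probs = probs, scores = probs[, 2], emb = emb, running = run)
  if (keep_cache) {
    out$cache <- list(pre = pre_caches,
                      bn = bn_caches, conv = conv_caches,
                      pool = pool_caches, blocks = block_meta, gap = gp$cache,
                      f1 = f1$cache, e1 = e1$cache, f2 = f2$cache,
                      e2 = e2$cache, fz = fz$cache, N = N)
  }
  out
}

# Backward pass from softmax-cross-entropy logit gradient dZ (N x n_classes).
cnn_backward_batch <- function(model, cache, dZ) {
  spec <- model$spec
  p <- model$params
  grads <- list()
  fzb <- dense_bwd(cache$fz, p$clf_W, dZ)
  grads$clf_W <- fzb$dW; grads$clf_b <- fzb$db
  d <- relu_bwd(cache$e2, fzb$dX)
  f2b <- dense_bwd(cache$f2, p$fc2_W, d)
  grads$fc2_W <- f2b$dW; grads$fc2_b <- f2b$db
  d <- relu_bwd(cache$e1, f2b$dX)
  f1b <- dense_bwd(cache$f1, p$fc1_W, d)
  grads$fc1_W <- f1b$dW; grads$fc1_b <- f1b$db
  d <- gap_bwd(cache$gap, f1b$dX)
  comp_bwd <- function(nm, d) {
    bb <- bn_relu_bwd(cache$bn[[nm]], d)
    grads[[paste0(nm, "_gamma")]] <<- bb$dgamma
    grads[[paste0(nm, "_beta")]] <<- bb$dbeta
    bb$dM
  }
  d <- comp_bwd("fin", d)
  nb <- length(spec$block_sizes)
  for (i in nb:1) {
    if (i < nb) {
      nm <- paste0("t", i)
      d <- pool2_bwd(cache$pool[[nm]], d)
      cb <- conv1_bwd(cache$conv[[nm]], d)
      grads[[paste0(nm, "_K")]] <- cb$dK
      grads[[paste0(nm, "_b")]] <- cb$db
      d <- comp_bwd(nm, cb$dM)
    }
    widths <- cache$blocks[[i]]$widths    # nrow of block input and each y_l
    Lb <- spec$block_sizes[i]
    splits <- vector("list", Lb + 1)
    off <- 0
    for (j in seq_len(Lb + 1)) {
      splits[[j]] <- d[off + seq_len(widths[j]), , drop = FALSE]
      off <- off + widths[j]
    }
    dy <- splits                          # dy[[1]] = d(block input), dy[[l+1]] = d(y_l)
    for (l in Lb:1) {
      nm <- paste0("b", i, "l", l)
      cb <- conv3_bwd(cache$conv[[nm]], dy[[l + 1]], need_dx = TRUE)
      grads[[paste0(nm, "_K")]] <- cb$dK
      grads[[paste0(nm, "_b")]] <- cb$db
      dy[[l]] <- dy[[l]] + comp_bwd(nm, cb$dM)
    }
    d <- dy[[1]]
  }
  # pre-conditioning: gradient only to the trainable convs (LoG input is data)
  ncs <- spec$convs_per_scale
  off <- 0
  for (s in seq_along(spec$log_sigmas)) {
    off <- off + 1                        # skip the fixed LoG channel
    dconv <- d[off + seq_len(ncs), , drop = FALSE]
    cb <- conv3_bwd(cache$pre[[s]], dconv, need_dx = FALSE)
    grads[[paste0("pre", s, "_K")]] <- cb$dK
    grads[[paste0("pre", s, "_b")]] <- cb$db
    off <- off + ncs
  }
  grads
}

#' Run the CNN on a single tile
#'
#' @param model a trained or initialized [build_base_cnn()].
#' @param tile a `spectrogram_tile` or bare 36 x 21 matrix of dB values.
#' @return list with `score` (positive-class probability), `probs` (both
#'   class probabilities, summing to 1) and `embedding` (32 values).
#'   Inference uses batch-norm running statistics and is deterministic.
#' @export
cnn_forward <- function(model, tile) {
  vals <- if (inherits(tile, "spectrogram_tile")) tile$values else tile
  out <- cnn_forward_batch(model, array(vals, c(dim(vals), 1)), training = FALSE)
  list(score = out$scores[1], probs = out$probs[1, ], embedding = out$emb[1, ])
}

#' Record frozen-CNN outputs for every tile on a grid
#'
#' Applies the trained base CNN once over an ordered tile set and stores the
#' (score, embedding) pairs that hybrid training and inference reuse; entries
#' are identical to direct [cnn_forward()] calls.
#'
#' @param model a [build_base_cnn()] result.
#' @param tiles 36 x 21 x n array in grid order.
#' @param batch_size inference batch size.
#' @return an object of class `cnn_output_cache` with fields `scores`
#'   (length n), `embeddings` (n x 32) and `n`.
#' @export
precompute_outputs <- function(model, tiles, batch_size = 256) {
  n <- dim(tiles)[3]
  scores <- numeric(n)
  embeddings <- matrix(NA_real_, n, model$spec$embedding_dim)
  i <- 1
  while (i <= n) {
    j <- min(i + batch_size - 1, n)
    out <- cnn_forward_batch(model, tiles[, , i:j, drop = FALSE], training = FALSE)
    scores[i:j] <- out$scores
    embeddings[i:j, ] <- out$emb
    i <- j + 1
  }
  structure(list(scores = scores, embeddings = embeddings, n = n),
            class = "cnn_output_cache")
}
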