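test_that("prediction-point index follows round-half-up within [1, T]", {
  expect_equal(pp_index(108, 1.00), 108)
  expect_equal(pp_index(108, 0.50), 54)
  expect_equal(pp_index(108, 0.67), 72)   # round(72.36)
  expect_equal(pp_index(88, 0.75), 66)
  expect_equal(pp_index(10, 0.05), 1)     # clamped
  expect_error(pp_index(108, 0), "pp_fraction")
  expect_error(pp_index(108, 1.2), "pp_fraction")
  expect_error(pp_index(1, 0.5), "time_steps")
})

test_that("input width follows the variant: 1, 32 or 33 with score last", {
  expect_equal(hybrid_config("SCORE")$input_dim, 1)
  expect_equal(hybrid_config("FEATURE")$input_dim, 32)
  expect_equal(hybrid_config("SCORE_PLUS_FEATURE")$input_dim, 33)

  cache <- structure(list(scores = runif(20), embeddings = matrix(rnorm(640), 20),
                          n = 20), class = "cnn_output_cache")
  labels <- rep("NEGATIVE", 20)
  for (v in c("SCORE", "FEATURE", "SCORE_PLUS_FEATURE")) {
    cfg <- hybrid_config(v, time_steps = 10, pp_fraction = 1)
    seqs <- assemble_sequences(cache, labels, cfg)
    expect_equal(dim(seqs$inputs)[2], cfg$input_dim)
  }
  # score sits in the last input column of the combined variant
  cfg <- hybrid_config("SCORE_PLUS_FEATURE", time_steps = 10, pp_fraction = 1)
  seqs <- assemble_sequences(cache, labels, cfg)
  expect_equal(seqs$inputs[1, 33, ], cache$scores[1:10])
})

test_that("window enumeration matches brute force and labels follow the PP segment", {
  set.seed(12)
  n <- 40
  cache <- structure(list(scores = runif(n), embeddings = matrix(rnorm(n * 32), n),
                          n = n), class = "cnn_output_cache")
  labels <- sample(c("POSITIVE", "NEGATIVE"), n, replace = TRUE)
  for (ppf in c(0.5, 1)) {
    cfg <- hybrid_config("SCORE", time_steps = 12, pp_fraction = ppf)
    seqs <- assemble_sequences(cache, labels, cfg, keep_partial_pp = TRUE)
    expect_equal(dim(seqs$inputs)[1], n - 12 + 1)
    p <- pp_index(12, ppf)
    expect_equal(seqs$pp_segment, seq_len(n - 11) + p - 1)
    expect_equal(seqs$labels,
                 as.numeric(labels[seqs$pp_segment] == "POSITIVE"))
  }
  # exactly T segments -> exactly one window
  cfgT <- hybrid_config("SCORE", time_steps = n, pp_fraction = 1)
  expect_equal(dim(assemble_sequences(cache, labels, cfgT)$inputs)[1], 1)
  # shorter than T -> zero windows with a warning
  cfgL <- hybrid_config("SCORE", time_steps = n + 1, pp_fraction = 1)
  expect_warning(z <- assemble_sequences(cache, labels, cfgL), "shorter")
  expect_equal(dim(z$inputs)[1], 0)
})

test_that("PARTIAL prediction points are excluded from training but scored at inference", {
  set.seed(13)
  n <- 30
  cache <- structure(list(scores = runif(n), embeddings = matrix(rnorm(n * 32), n),
                          n = n), class = "cnn_output_cache")
  labels <- rep("NEGATIVE", n)
  labels[c(15, 16)] <- "PARTIAL"
  cfg <- hybrid_config("SCORE", time_steps = 10, pp_fraction = 1)
  train_seqs <- assemble_sequences(cache, labels, cfg)
  expect_false(any(train_seqs$pp_segment %in% c(15, 16)))
  infer_seqs <- assemble_sequences(cache, labels, cfg, keep_partial_pp = TRUE)
  expect_true(all(c(15, 16) %in% infer_seqs$pp_segment))
  expect_true(anyNA(infer_seqs$labels))
})

test_that("hybrid heads emit deterministic sigmoid scores", {
  cfg <- hybrid_config("SCORE_PLUS_FEATURE", time_steps = 20, pp_fraction = 0.5)
  head <- build_hybrid_head(cfg, seed = 5)
  set.seed(14)
  X <- matrix(rnorm(33 * 20), 33, 20)
  s <- hybrid_score(head, X)
  expect_gte(s, 0); expect_lte(s, 1)
  expect_identical(hybrid_score(head, X), s)
  expect_identical(build_hybrid_head(cfg, seed = 5)$params, head$params)
})

test_that("a window of T segments spans (T-1) * hop + segment seconds", {
  expect_equal((108 - 1) * 1 + 4, 111)
  g <- make_segment_grid(111, 4, 1)
  expect_equal(g$n_segments, 108)
  expect_equal((88 - 1) * 1.25 + 4, 112.75)
  expect_equal(make_segment_grid(112.75, 4, 1.25)$n_segments, 88)
})

test_that("stream detection aligns scores with prediction-point segments", {
  set.seed(15)
  rec <- waveform_recording(rnorm(500 * 30), 500, source_id = "stream")
  cnn <- build_base_cnn(seed = 1)
  cfg <- hybrid_config("SCORE", time_steps = 20, pp_fraction = 1)
  head <- build_hybrid_head(cfg, seed = 1)
  det <- detect_stream(cnn, head, rec)
  n_seg <- 27  # floor((30 - 4) / 1) + 1
  expect_equal(nrow(det), n_seg)
  expect_equal(det$segment_start_s, 0:(n_seg - 1))
  # PP at 100%: first 19 segments lack full context
  expect_true(all(is.na(det$score[1:19])))
  expect_true(all(!is.na(det$score[20:n_seg])))
  expect_true(all(!is.na(det$cnn_score)))
  # centered PP shifts the scored span
  head50 <- build_hybrid_head(hybrid_config("SCORE", time_steps = 20,
                                            pp_fraction = 0.5), seed = 1)
  det50 <- detect_stream(cnn, head50, rec)
  expect_true(all(!is.na(det50$score[10:17])))
  expect_true(all(is.na(det50$score[1:9])))
  # too-short recording
  expect_warning(
    empty <- detect_stream(cnn, head, waveform_recording(rnorm(500 * 10), 500)),
    "shorter")
  expect_equal(nrow(empty), 0)
})
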