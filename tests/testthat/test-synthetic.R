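test_that("synthetic pulses are in-band downsweeps of the requested length", {
  p <- synth_pulse(pulse_spec(), 500)
  expect_length(p, 500)
  o <- dft_power(p, 500)
  peak <- o$freq[which.max(o$power)]
  expect_gte(peak, 17); expect_lte(peak, 23)
  # downsweep: dominant frequency of the first half exceeds the second half
  o1 <- dft_power(p[1:250], 500)
  o2 <- dft_power(p[251:500], 500)
  expect_gt(o1$freq[which.max(o1$power)], o2$freq[which.max(o2$power)])
  expect_error(pulse_spec(f_start_hz = 17, f_end_hz = 23), "downswept")
  expect_error(synth_pulse(pulse_spec(), 40), "Nyquist")
})

test_that("doublet songs alternate their two INIs from the start time", {
  sp <- song_spec("DOUBLET", c(16.9, 21.5), ini_jitter_sd_s = 0, n_notes = 5)
  song <- synth_song(sp, start_s = 0, seed = 1)
  expect_equal(song$begins_s, c(0, 16.9, 38.4, 55.3, 76.8))
  expect_equal(nrow(song$annotations), 5)
  expect_equal(song$annotations$end_s - song$annotations$begin_s, rep(1, 5))
  one <- synth_song(song_spec("SINGLET", 20, n_notes = 1), 0, 1)
  expect_equal(nrow(compute_inis(one$annotations)), 0)
})

test_that("generated INI distributions peak at the doublet intervals", {
  set.seed(40)
  inis <- unlist(lapply(1:200, function(i) {
    s <- synth_song(song_spec("DOUBLET", c(16.9, 21.5), ini_jitter_sd_s = 0.3,
                              n_notes = 6), 0, seed = i)
    compute_inis(s$annotations)$value_s
  }))
  short_mode <- mean(inis[inis < 19.2])
  long_mode <- mean(inis[inis >= 19.2])
  expect_lt(abs(short_mode - 16.9), 0.2)
  expect_lt(abs(long_mode - 21.5), 0.2)
})

test_that("soundscapes are bit-identical under identical seeds", {
  spec <- soundscape_spec(
    duration_s = 60,
    ship_events = data.frame(start_s = 10, duration_s = 15, level_db = 8),
    songs = list(list(spec = song_spec(n_notes = 3), start_s = 5)),
    seed = 99)
  a <- synth_soundscape(spec)
  b <- synth_soundscape(spec)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$annotations, b$annotations)
  expect_equal(nrow(a$annotations), 3)
  expect_equal(nrow(a$manifest$notes), 3)
})

test_that("rendered notes hit their requested in-band SNR within 1.5 dB", {
  sc <- asNamespace("songcontext")
  base <- soundscape_spec(duration_s = 120, songs = list(), seed = 7)
  with_song <- soundscape_spec(
    duration_s = 120,
    songs = list(list(spec = song_spec("DOUBLET", c(16.9, 21.5),
                                       ini_jitter_sd_s = 0, n_notes = 4,
                                       snr_db = c(6, 0, 10, 3)), start_s = 10)),
    seed = 7)
  quiet <- synth_soundscape(base)$recording$samples
  loud <- synth_soundscape(with_song)
  notes <- loud$manifest$notes
  fs <- 500
  for (k in seq_len(nrow(notes))) {
    span <- (round(notes$begin_s[k] * fs) + 1):(round(notes$begin_s[k] * fs) + fs)
    sig <- loud$recording$samples[span] - quiet[span]
    measured <- 20 * log10(sc$.inband_rms(sig, fs) / sc$.inband_rms(quiet[span], fs))
    expect_lt(abs(measured - notes$snr_db[k]), 1.5)
  }
})

test_that("overlapping songs are permitted and flagged", {
  spec <- soundscape_spec(
    duration_s = 80,
    songs = list(list(spec = song_spec(n_notes = 3), start_s = 5),
                 list(spec = song_spec(n_notes = 3), start_s = 5.5)),
    seed = 3)
  out <- synth_soundscape(spec)
  expect_true(out$manifest$overlapping_songs)
  expect_equal(nrow(out$annotations), 6)
})

test_that("generator annotations and the labelling pipeline agree end-to-end", {
  spec <- soundscape_spec(
    duration_s = 120,
    songs = list(list(spec = song_spec("DOUBLET", c(16.9, 21.5), n_notes = 5,
                                       snr_db = 12), start_s = 8)),
    seed = 11)
  out <- synth_soundscape(spec)
  ext <- extract_tiles(out$recording)
  labels <- label_segments(ext$grid, out$annotations)
  # every rendered note is fully contained in at least one POSITIVE segment
  for (k in seq_len(nrow(out$annotations))) {
    b <- out$annotations$begin_s[k]; e <- out$annotations$end_s[k]
    covering <- which(ext$grid$start_times_s <= b &
                        e <= ext$grid$start_times_s + 4)
    expect_true(all(labels[covering] == "POSITIVE"))
    expect_gt(length(covering), 0)
  }
})

test_that("the benchmark recipe is internally consistent and stresses low SNR", {
  ds <- make_benchmark_dataset(seed = 5, rec_duration_s = 120,
                               train_base_snr_db = c(4, 8),
                               test_doublet_snr_db = c(-2),
                               test_singlet_snr_db = c(2))
  expect_equal(length(ds$train), 4)   # 2 song + 2 noise recordings
  expect_equal(length(ds$test), 2)
  for (r in c(ds$train, ds$test))
    expect_equal(recording_duration(r$recording), 120)
  # test split reaches below the training SNR minimum
  expect_lt(ds$recipe$test_min_snr_db, ds$recipe$train_min_snr_db)
  # labels exist for every rendered note
  for (r in ds$test[1]) {
    if (nrow(r$annotations) == 0) next
    expect_gt(sum(r$labels == "POSITIVE"), 0)
  }
})
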