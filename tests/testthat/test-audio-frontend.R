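test_that("resampling preserves duration and handles the identity case", {
  rec <- waveform_recording(sin(2 * pi * 10 * (0:1999999) / 200000), 200000)
  out <- resample_to_working_rate(rec, 500)
  expect_equal(out$sample_rate_hz, 500)
  expect_equal(length(out$samples), 5000)   # 10 s at 500 Hz

  rec500 <- waveform_recording(rnorm(1000), 500)
  expect_identical(resample_to_working_rate(rec500, 500)$samples,
                   rec500$samples)

  expect_error(waveform_recording(numeric(0), 500), "at least one sample")
  expect_error(waveform_recording(c(1, NA), 500), "finite")
})

test_that("anti-alias filtering suppresses out-of-band energy by >= 40 dB", {
  fs_in <- 2000
  t <- (0:(10 * fs_in - 1)) / fs_in
  x <- sin(2 * pi * 300 * t) + 0.5 * sin(2 * pi * 50 * t)
  out <- resample_to_working_rate(waveform_recording(x, fs_in), 500)
  n <- length(out$samples)
  spec <- Mod(stats::fft(out$samples))^2
  f <- (0:(n - 1)) * 500 / n
  # 300 Hz aliases to 200 Hz after decimation to 500 Hz
  passband <- max(spec[f > 45 & f < 55])
  stopband <- max(spec[f > 150 & f <= 250])
  expect_gt(10 * log10(passband / stopband), 40)
  # the in-band 50 Hz tone survives: compare against a DFT oracle of the input
  oin <- dft_power(x[1:4000], fs_in)
  expect_equal(oin$freq[which.max(oin$power)], 300)  # input dominated by 300 Hz
  oout <- dft_power(out$samples[1:1000], 500)
  expect_lt(abs(oout$freq[which.max(oout$power)] - 50), 1)
})

test_that("segment grid counts match the hop arithmetic and the enumeration oracle", {
  g <- make_segment_grid(111, 4, 1)
  expect_equal(g$n_segments, 108)
  expect_equal(make_segment_grid(112.75, 4, 1.25)$n_segments, 88)
  g1 <- make_segment_grid(4, 4, 1)
  expect_equal(g1$n_segments, 1)
  expect_equal(g1$start_times_s, 0)
  expect_equal(make_segment_grid(3.5, 4, 1)$n_segments, 0)
  expect_error(make_segment_grid(10, 1, 4), "hop")

  set.seed(11)
  for (i in 1:200) {
    seg <- runif(1, 1, 10)
    hop <- runif(1, 0.1, seg * 0.99)
    dur <- runif(1, seg, 60)
    g <- make_segment_grid(dur, seg, hop)
    # oracle: enumerate starts directly
    starts <- seq(0, by = hop, length.out = 10000)
    n_oracle <- sum(starts + seg <= dur + 1e-9)
    expect_equal(g$n_segments, n_oracle)
    if (g$n_segments > 1)
      expect_equal(diff(g$start_times_s), rep(hop, g$n_segments - 1))
    expect_true(all(g$start_times_s + seg <= dur + 1e-9))
  }
})

test_that("any event no longer than segment - hop is fully covered by some segment", {
  set.seed(21)
  g <- make_segment_grid(60, 4, 1)
  for (i in 1:200) {
    len <- runif(1, 0.05, 3)
    b <- runif(1, 0, 56 - len)
    covered <- any(g$start_times_s <= b &
                     b + len <= g$start_times_s + g$segment_duration_s)
    expect_true(covered)
  }
})

test_that("amplitude normalization scales to [-1, 1] and is idempotent", {
  expect_equal(normalize_amplitude(c(0.5, -0.25)), c(1, -0.5))
  expect_equal(normalize_amplitude(rep(0, 10)), rep(0, 10))
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(100) * 10^runif(1, -3, 3)
    nx <- normalize_amplitude(x)
    expect_equal(max(abs(nx)), 1)
    expect_equal(normalize_amplitude(nx), nx)
    expect_equal(normalize_amplitude(runif(1, 0.1, 10) * x), nx)
  }
})

test_that("PSD tiles have the pinned 36 x 21 geometry at 1.25 Hz spacing", {
  set.seed(5)
  tile <- compute_psd_tile(normalize_amplitude(rnorm(2000)))
  expect_equal(dim(tile$values), c(36, 21))
  expect_equal(diff(tile$freq_bin_centers_hz), rep(1.25, 35))
  expect_equal(tile$freq_bin_centers_hz[1], 10)
  expect_equal(length(tile$frame_times_s), 21)
  expect_true(all(is.finite(tile$values)))
  expect_error(compute_psd_tile(rnorm(1999)), "expected 2000")
})

test_that("a pure 20 Hz tone peaks in the 20 Hz bin, matching a DFT oracle", {
  x <- normalize_amplitude(sin(2 * pi * 20 * (0:1999) / 500))
  tile <- compute_psd_tile(x)
  peak_row <- which.max(rowMeans(tile$values))
  expect_equal(tile$freq_bin_centers_hz[peak_row], 20)
  # oracle: direct DFT of one Hann-windowed frame
  w <- 0.5 - 0.5 * cos(2 * pi * (0:399) / 399)
  o <- dft_power(x[1:400] * w, 500)
  expect_equal(o$freq[which.max(o$power)], 20)
})

test_that("tile geometry is hop-invariant (grid changes, tile does not)", {
  set.seed(6)
  rec <- waveform_recording(rnorm(500 * 20), 500)
  for (hop in c(1, 1.25)) {
    ext <- extract_tiles(rec, hop_s = hop)
    expect_equal(dim(ext$tiles)[1:2], c(36, 21))
    expect_equal(ext$grid$n_segments,
                 floor((20 - 4) / hop) + 1)
  }
})

test_that("WAV files round-trip through write and read", {
  set.seed(7)
  x <- runif(1000, -0.9, 0.9)
  path <- tempfile(fileext = ".wav")
  write_wav(waveform_recording(x, 500, source_id = "t"), path)
  back <- read_wav(path)
  expect_equal(back$sample_rate_hz, 500)
  expect_equal(back$samples, x, tolerance = 1e-6)
  write_wav(waveform_recording(x, 500), path, bits = 16)
  back16 <- read_wav(path)
  expect_equal(back16$samples, x, tolerance = 1e-4)
})
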