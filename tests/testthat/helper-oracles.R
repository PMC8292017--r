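# Shared test utilities: independent brute-force oracles and tiny fixtures.

# Direct DFT power spectrum (oracle, independent of the package's STFT path).
dft_power <- function(x, fs) {
  n <- length(x)
  f <- (0:(n - 1)) * fs / n
  p <- Mod(vapply(seq_len(n), function(k) {
    sum(x * exp(-2i * pi * (k - 1) * (0:(n - 1)) / n))
  }, complex(1)))^2
  keep <- f <= fs / 2
  data.frame(freq = f[keep], power = p[keep])
}

# Brute-force average precision: direct counting at every distinct threshold.
brute_auc_pr <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_r <- 0
  area <- 0
  for (t in thr) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    p <- tp / (tp + fp)
    r <- tp / n_pos
    area <- area + (r - prev_r) * p
    prev_r <- r
  }
  area
}

brute_peak_f1 <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  best <- 0
  for (t in thr) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    fn <- sum(scores < t & labels == 1)
    f1 <- 2 * tp / max(2 * tp + fp + fn, 1)
    if (f1 > best) best <- f1
  }
  best
}

# A small spectrogram tile containing a synthetic note at a known frequency,
# built through the package's own front end on generated audio.
make_note_tile <- function(f_center = 20, snr_db = 20, seed = 1) {
  set.seed(seed)
  fs <- 500
  noise <- rnorm(4 * fs) * 10^(-snr_db / 20)
  pulse <- synth_pulse(pulse_spec(f_start_hz = f_center + 3,
                                  f_end_hz = f_center - 3), fs)
  x <- noise
  x[751:(750 + length(pulse))] <- x[751:(750 + length(pulse))] + pulse
  compute_psd_tile(normalize_amplitude(x))
}

# Random tiles + separable labels for quick training smoke tests: positives
# carry an energetic band near 20 Hz, negatives are noise-only.
make_toy_tiles <- function(n, p_pos = 0.5, seed = 1) {
  set.seed(seed)
  labels <- ifelse(runif(n) < p_pos, "POSITIVE", "NEGATIVE")
  tiles <- array(NA_real_, c(36, 21, n))
  fs <- 500
  for (i in seq_len(n)) {
    x <- rnorm(4 * fs)
    if (labels[i] == "POSITIVE") {
      pulse <- synth_pulse(sample_rate_hz = fs)
      at <- sample(500:1400, 1)
      x[at:(at + 499)] <- x[at:(at + 499)] + pulse * 8
    }
    tiles[, , i] <- compute_psd_tile(normalize_amplitude(x))$values
  }
  list(tiles = tiles, labels = labels)
}
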