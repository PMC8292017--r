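#' Waveform recording container
#'
#' A single-channel amplitude series with its sampling rate, an opaque source
#' identifier, and the offset of the first sample from the start of the
#' original file.
#'
#' @param samples numeric amplitude series (dimensionless); must be finite and
#'   non-empty.
#' @param sample_rate_hz sampling rate in Hz, > 0.
#' @param source_id opaque recording identifier.
#' @param start_offset_s seconds from file start to the first sample.
#' @return an object of class `waveform_recording`.
#' @export
waveform_recording <- function(samples, sample_rate_hz, source_id = "unknown",
                               start_offset_s = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("invalid input: recording must contain at least one sample")
  if (!all(is.finite(samples))) stop("invalid input: samples must be finite")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L || sample_rate_hz <= 0)
    stop("invalid input: sample_rate_hz must be a positive scalar")
  structure(
    list(samples = samples, sample_rate_hz = sample_rate_hz,
         source_id = source_id, start_offset_s = start_offset_s),
    class = "waveform_recording")
}

#' @export
print.waveform_recording <- function(x, ...) {
  cat(sprintf("<waveform_recording> %s: %.2f s at %g Hz\n",
              x$source_id, length(x$samples) / x$sample_rate_hz, x$sample_rate_hz))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a [waveform_recording()].
#' @export
recording_duration <- function(rec) length(rec$samples) / rec$sample_rate_hz

# Greedy factorization of an integer decimation ratio into stages <= 10,
# keeping each zero-phase Chebyshev stage well inside its stable range.
.decimation_stages <- function(q) {
  stages <- integer(0)
  r <- q
  while (r > 1) {
    f <- NA_integer_
    for (cand in 10:2) if (r %% cand == 0) { f <- cand; break }
    if (is.na(f)) { f <- r } # prime > 10; single stage, still acceptable
    stages <- c(stages, f)
    r <- r %/% f
  }
  sort(stages, decreasing = TRUE)
}

#' Resample a recording to the working rate
#'
#' Brings a recording to the common analysis rate (500 Hz by default
#' throughout the package) with zero-phase anti-alias filtering. Integer
#' decimation ratios are handled by staged zero-phase Chebyshev decimation
#' ([signal::decimate] with `filtfilt`); other rational ratios fall back to
#' polyphase resampling ([signal::resample]).
#'
#' @param rec a [waveform_recording()].
#' @param target_hz the working sampling rate (Hz, > 0).
#' @return a [waveform_recording()] at `target_hz`; duration is preserved to
#'   within one sample period. Upsampling is permitted but flagged with a
#'   message, since the intended workflows only downsample.
#' @export
resample_to_working_rate <- function(rec, target_hz = 500) {
  if (!inherits(rec, "waveform_recording")) stop("invalid input: rec must be a waveform_recording")
  if (!is.numeric(target_hz) || target_hz <= 0) stop("invalid input: target_hz must be > 0")
  fs <- rec$sample_rate_hz
  if (isTRUE(all.equal(fs, target_hz))) return(rec)
  if (target_hz > fs) message("upsampling from ", fs, " Hz to ", target_hz, " Hz")

  # rational ratio target/fs = p/q in lowest terms (rates taken to mHz grid)
  a <- round(target_hz * 1000); b <- round(fs * 1000)
  g <- .gcd(a, b); p <- a / g; q <- b / g
  x <- rec$samples
  if (p == 1 && q > 1) {
    for (f in .decimation_stages(q)) {
      x <- signal::decimate(x, f, ftype = "iir")
    }
  } else {
    x <- signal::resample(rec$samples, p, q)
  }
  waveform_recording(x, target_hz, source_id = rec$source_id,
                     start_offset_s = rec$start_offset_s)
}

.gcd <- function(a, b) { while (b) { t <- b; b <- a %% b; a <- t }; a }

#' Overlapping segment grid over a recording
#'
#' Cuts the analysis grid of fixed-duration segments advanced by a constant
#' hop. With the 4 s / 1 s defaults every note no longer than 3 s is fully
#' contained in at least one segment. Trailing audio shorter than one segment
#' is dropped.
#'
#' @param duration_s recording duration (s).
#' @param segment_duration_s segment length (s), default 4.
#' @param hop_s grid advance (s), default 1 (1.25 in the coarser-granularity
#'   experiment).
#' @return an object of class `segment_grid` with fields `segment_duration_s`,
#'   `hop_s`, `start_times_s` and `n_segments`. A recording shorter than one
#'   segment yields an empty grid (zero segments), not an error.
#' @export
make_segment_grid <- function(duration_s, segment_duration_s = 4, hop_s = 1) {
  if (segment_duration_s <= 0 || hop_s <= 0 || segment_duration_s <= hop_s)
    stop("invalid input: need segment_duration_s > hop_s > 0")
  if (duration_s < segment_duration_s) {
    starts <- numeric(0)
  } else {
    n <- floor((duration_s - segment_duration_s) / hop_s + 1e-9) + 1
    starts <- (seq_len(n) - 1) * hop_s
  }
  structure(
    list(segment_duration_s = segment_duration_s, hop_s = hop_s,
         start_times_s = starts, n_segments = length(starts)),
    class = "segment_grid")
}

#' @export
print.segment_grid <- function(x, ...) {
  cat(sprintf("<segment_grid> %d segments of %g s, hop %g s\n",
              x$n_segments, x$segment_duration_s, x$hop_s))
  invisible(x)
}

#' Normalize segment amplitudes to [-1, 1]
#'
#' Scales a segment by a single positive constant so its maximum absolute
#' value is 1. An all-zero segment is returned unchanged (documented
#' degenerate case).
#'
#' @param segment_samples numeric amplitude series.
#' @return the scaled series.
#' @export
normalize_amplitude <- function(segment_samples) {
  if (!all(is.finite(segment_samples))) stop("invalid input: samples must be finite")
  m <- max(abs(segment_samples))
  if (m == 0) return(segment_samples)
  segment_samples / m
}

#' Band-limited PSD spectrogram tile for one segment
#'
#' Computes the power-spectral-density spectrogram of a 4 s segment at 500 Hz:
#' Hann-windowed 0.8 s frames (400 samples) with 80% overlap (hop 80 samples)
#' give 21 frames at 1.25 Hz frequency resolution; the band is trimmed to the
#' 36 bins with centers in [10, 53.75] Hz. Values are periodogram power in dB
#' relative to the tile maximum, floored at -120 dB.
#'
#' @param segment_samples a normalized segment of exactly
#'   `segment_duration_s * sample_rate_hz` samples.
#' @param sample_rate_hz working rate (default 500 Hz).
#' @param segment_duration_s segment length (default 4 s).
#' @param frame_duration_s analysis frame length (default 0.8 s).
#' @param frame_overlap_fraction frame overlap (default 0.8).
#' @param band_low_hz,band_high_hz retained band (defaults 10 and 54 Hz; bins
#'   with centers in `[band_low_hz, band_high_hz)` are kept).
#' @param segment_index grid position carried along for bookkeeping.
#' @return an object of class `spectrogram_tile` with fields `values` (36 x 21
#'   matrix, frequency x time), `freq_bin_centers_hz`, `frame_times_s` and
#'   `segment_index`.
#' @export
compute_psd_tile <- function(segment_samples, sample_rate_hz = 500,
                             segment_duration_s = 4, frame_duration_s = 0.8,
                             frame_overlap_fraction = 0.8,
                             band_low_hz = 10, band_high_hz = 54,
                             segment_index = NA_integer_) {
  n_expected <- round(segment_duration_s * sample_rate_hz)
  if (length(segment_samples) != n_expected)
    stop("invalid input: expected ", n_expected, " samples, got ", length(segment_samples))
  nf <- round(frame_duration_s * sample_rate_hz)            # 400
  hop <- round(nf * (1 - frame_overlap_fraction))           # 80
  n_frames <- (n_expected - nf) %/% hop + 1                 # 21
  starts <- (seq_len(n_frames) - 1) * hop
  frames <- vapply(starts, function(s) segment_samples[(s + 1):(s + nf)],
                   numeric(nf))
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nf - 1)) / (nf - 1))    # Hann
  spec <- stats::mvfft(frames * w)
  # one-sided periodogram PSD scaling
  psd <- (Mod(spec)^2) / (sample_rate_hz * sum(w^2))
  psd[2:(nf %/% 2), ] <- 2 * psd[2:(nf %/% 2), ]
  freqs <- (0:(nf - 1)) * sample_rate_hz / nf
  keep <- which(freqs >= band_low_hz & freqs < band_high_hz)
  vals <- psd[keep, , drop = FALSE]
  db <- 10 * log10(pmax(vals, 1e-30))
  db <- pmax(db - max(db), -120)
  structure(
    list(values = db, freq_bin_centers_hz = freqs[keep],
         frame_times_s = starts / sample_rate_hz + frame_duration_s / 2,
         segment_index = segment_index),
    class = "spectrogram_tile")
}

#' Cut a recording into grid segments and compute all tiles
#'
#' Convenience wrapper running [make_segment_grid()], [normalize_amplitude()]
#' and [compute_psd_tile()] over a whole recording at the working rate.
#'
#' @param rec a [waveform_recording()] at `sample_rate_hz`.
#' @param segment_duration_s,hop_s grid parameters.
#' @param ... passed to [compute_psd_tile()].
#' @return list with `grid` (a `segment_grid`) and `tiles` (36 x 21 x
#'   n_segments array of dB values).
#' @export
extract_tiles <- function(rec, segment_duration_s = 4, hop_s = 1, ...) {
  fs <- rec$sample_rate_hz
  grid <- make_segment_grid(recording_duration(rec), segment_duration_s, hop_s)
  seg_len <- round(segment_duration_s * fs)
  tiles <- array(NA_real_, c(36, 21, grid$n_segments))
  for (i in seq_len(grid$n_segments)) {
    s0 <- round(grid$start_times_s[i] * fs)
    seg <- normalize_amplitude(rec$samples[(s0 + 1):(s0 + seg_len)])
    tiles[, , i] <- compute_psd_tile(seg, sample_rate_hz = fs,
                                     segment_duration_s = segment_duration_s,
                                     segment_index = i, ...)$values
  }
  list(grid = grid, tiles = tiles)
}
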