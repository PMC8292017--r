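#' Synthetic note (pulse) specification
#'
#' A stereotyped ~1 s downswept pulse with energy centered near 20 Hz,
#' modelled as a linear chirp under a Tukey taper; both sweep endpoints must
#' lie inside the 10-54 Hz analysis band and the sweep must be downward.
#'
#' @param duration_s pulse duration (s).
#' @param f_start_hz,f_end_hz sweep endpoints (Hz), `f_start_hz > f_end_hz`.
#' @param taper Tukey taper fraction in \[0, 1\].
#' @param amplitude linear amplitude scale.
#' @return a `pulse_spec` list.
#' @export
pulse_spec <- function(duration_s = 1.0, f_start_hz = 23, f_end_hz = 17,
                       taper = 0.25, amplitude = 1.0) {
  if (f_start_hz <= f_end_hz) stop("invalid input: pulse must be downswept")
  if (f_start_hz > 54 || f_end_hz < 10)
    stop("invalid input: sweep must stay within the 10-54 Hz band")
  structure(list(duration_s = duration_s, f_start_hz = f_start_hz,
                 f_end_hz = f_end_hz, taper = taper, amplitude = amplitude),
            class = "pulse_spec")
}

#' Synthesize one pulse
#'
#' Linear-frequency chirp from `f_start_hz` down to `f_end_hz` under a Tukey
#' envelope; the instantaneous frequency decreases monotonically by
#' construction of the phase law.
#'
#' @param spec a [pulse_spec()].
#' @param sample_rate_hz sampling rate (>= 500 Hz recommended).
#' @return numeric amplitude series of `round(duration_s * sample_rate_hz)`
#'   samples.
#' @export
synth_pulse <- function(spec = pulse_spec(), sample_rate_hz = 500) {
  if (spec$f_start_hz >= sample_rate_hz / 2)
    stop("invalid input: sweep exceeds Nyquist frequency")
  n <- round(spec$duration_s * sample_rate_hz)
  t <- (0:(n - 1)) / sample_rate_hz
  k <- (spec$f_end_hz - spec$f_start_hz) / spec$duration_s
  phase <- 2 * pi * (spec$f_start_hz * t + 0.5 * k * t^2)
  x <- sin(phase)
  x * .tukey(n, spec$taper) * spec$amplitude
}

.tukey <- function(n, a) {
  if (a <= 0) return(rep(1, n))
  w <- rep(1, n)
  edge <- floor(a * (n - 1) / 2)
  i <- 0:edge
  ramp <- 0.5 * (1 + cos(pi * (2 * i / (a * (n - 1)) - 1)))
  w[i + 1] <- ramp
  w[n - i] <- ramp
  w
}

#' Song specification
#'
#' @param pattern `"SINGLET"` (one distinct INI), `"DOUBLET"` (two
#'   alternating INIs; the regionally dominant type with INIs near 16.9 s
#'   and 21.5 s) or `"TRIPLET"`.
#' @param ini_values_s the distinct INIs (s); arity must match the pattern.
#' @param ini_jitter_sd_s Gaussian jitter on each realized INI (s).
#' @param n_notes number of notes.
#' @param snr_db per-note in-band SNR targets: one value (all notes), a
#'   length-`n_notes` vector, or a function(n) drawing n values.
#' @param pulse a [pulse_spec()].
#' @return a `song_spec` list.
#' @export
song_spec <- function(pattern = c("DOUBLET", "SINGLET", "TRIPLET"),
                      ini_values_s = c(16.9, 21.5), ini_jitter_sd_s = 0.3,
                      n_notes = 10, snr_db = 6, pulse = pulse_spec()) {
  pattern <- match.arg(pattern)
  need <- switch(pattern, SINGLET = 1L, DOUBLET = 2L, TRIPLET = 3L)
  if (pattern == "TRIPLET") {
    if (length(ini_values_s) < 2) stop("invalid input: TRIPLET needs >= 2 INIs")
  } else if (length(ini_values_s) != need)
    stop("invalid input: ", pattern, " needs exactly ", need, " INI value(s)")
  if (any(ini_values_s <= 0)) stop("invalid input: INIs must be positive")
  structure(list(pattern = pattern, ini_values_s = ini_values_s,
                 ini_jitter_sd_s = ini_jitter_sd_s, n_notes = n_notes,
                 snr_db = snr_db, pulse = pulse),
            class = "song_spec")
}

#' Place the notes of one song
#'
#' Note k+1 begins INI(k) seconds (plus jitter) after note k, start-to-start,
#' with the INI sequence cycling through the pattern's distinct values.
#' Jitter that would make an INI non-positive is redrawn with a warning.
#'
#' @param spec a [song_spec()].
#' @param start_s begin time of the first note (s).
#' @param seed RNG seed.
#' @return list with `begins_s`, `snr_db` (per note) and `annotations`
#'   (a [note_annotations()] data frame with exact synthesis bounds).
#' @export
synth_song <- function(spec, start_s = 0, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- spec$n_notes
  ini_seq <- rep_len(spec$ini_values_s, max(n - 1, 0))
  begins <- numeric(n)
  begins[1] <- start_s
  if (n > 1) for (k in 2:n) {
    ini <- ini_seq[k - 1] + stats::rnorm(1, 0, spec$ini_jitter_sd_s)
    tries <- 0
    while (ini <= spec$pulse$duration_s && tries < 100) {
      warning("non-positive effective INI after jitter; resampled")
      ini <- ini_seq[k - 1] + stats::rnorm(1, 0, spec$ini_jitter_sd_s)
      tries <- tries + 1
    }
    begins[k] <- begins[k - 1] + ini
  }
  snr <- if (is.function(spec$snr_db)) spec$snr_db(n) else rep_len(spec$snr_db, n)
  ann <- note_annotations(begin_s = begins,
                          end_s = begins + spec$pulse$duration_s,
                          low_hz = spec$pulse$f_end_hz,
                          high_hz = spec$pulse$f_start_hz)
  list(begins_s = begins, snr_db = snr, annotations = ann)
}

#' Soundscape specification
#'
#' @param duration_s total duration (s).
#' @param ambient_level ambient noise RMS (linear).
#' @param ship_events data frame with `start_s`, `duration_s`, `level_db`
#'   (dB above ambient) describing band-limited (10-100 Hz) slowly
#'   amplitude-modulated interference bursts; `NULL` for none.
#' @param songs list of `list(spec = song_spec, start_s = ...)` entries.
#' @param seed RNG seed fixing every random draw.
#' @return a `soundscape_spec` list.
#' @export
soundscape_spec <- function(duration_s = 300, ambient_level = 1,
                            ship_events = NULL, songs = list(), seed = 1) {
  if (!is.null(ship_events))
    stopifnot(all(ship_events$start_s + ship_events$duration_s <= duration_s))
  structure(list(duration_s = duration_s, ambient_level = ambient_level,
                 ship_events = ship_events, songs = songs, seed = seed),
            class = "soundscape_spec")
}

# Low-frequency-shaped Gaussian ambient noise (2nd-order Butterworth lowpass).
.ambient_noise <- function(n, fs, level) {
  bw <- signal::butter(2, 100 / (fs / 2), type = "low")
  x <- signal::filter(bw, stats::rnorm(n))
  x <- as.numeric(x)
  x / stats::sd(x) * level
}

# In-band (10-54 Hz) RMS of a series via zero-phase Butterworth bandpass.
.inband_rms <- function(x, fs) {
  bp <- signal::butter(4, c(10, 54) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  sqrt(mean(xf^2))
}

#' Render an annotated synthetic soundscape
#'
#' Mixes low-frequency-shaped ambient Gaussian noise, optional ship-like
#' interference bursts, and song pulse trains. Each note is scaled so that
#' its in-band (10-54 Hz) RMS, relative to the in-band ambient-plus-ship
#' noise RMS measured over the note's span, matches the requested per-note
#' SNR. Output is bit-identical under identical seeds. Overlapping songs are
#' permitted (concurrent-singer stress case) and flagged in the manifest.
#'
#' @param spec a [soundscape_spec()].
#' @param sample_rate_hz output rate (default 500 Hz).
#' @return list with `recording` (a [waveform_recording()]), `annotations`
#'   (all notes, chronological) and `manifest` (per-note song index, begin,
#'   requested SNR; plus an `overlapping_songs` flag).
#' @export
synth_soundscape <- function(spec, sample_rate_hz = 500) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  fs <- sample_rate_hz
  n <- round(spec$duration_s * fs)
  noise <- .ambient_noise(n, fs, spec$ambient_level)
  if (!is.null(spec$ship_events)) {
    bp <- signal::butter(4, c(10, 100) / (fs / 2), type = "pass")
    for (i in seq_len(nrow(spec$ship_events))) {
      ev <- spec$ship_events[i, ]
      m <- round(ev$duration_s * fs)
      burst <- as.numeric(signal::filtfilt(bp, stats::rnorm(m)))
      am <- 1 + 0.5 * sin(2 * pi * 0.05 * (0:(m - 1)) / fs +
                            stats::runif(1, 0, 2 * pi))
      burst <- burst / stats::sd(burst) * spec$ambient_level *
        10^(ev$level_db / 20) * am
      i0 <- round(ev$start_s * fs)
      noise[(i0 + 1):(i0 + m)] <- noise[(i0 + 1):(i0 + m)] + burst
    }
  }
  mix <- noise
  all_ann <- list(); manifest <- list()
  song_seeds <- sample.int(1e6, max(length(spec$songs), 1))
  spans <- matrix(NA_real_, 0, 2)
  for (si in seq_along(spec$songs)) {
    entry <- spec$songs[[si]]
    song <- synth_song(entry$spec, start_s = entry$start_s, seed = song_seeds[si])
    pulse_proto <- synth_pulse(entry$spec$pulse, fs)
    pulse_band_rms <- sqrt(mean(pulse_proto^2))  # chirp energy is in-band
    for (k in seq_along(song$begins_s)) {
      b <- song$begins_s[k]
      i0 <- round(b * fs)
      if (i0 + length(pulse_proto) > n) next
      span <- (i0 + 1):(i0 + length(pulse_proto))
      noise_rms <- .inband_rms(noise[span], fs)
      gain <- 10^(song$snr_db[k] / 20) * noise_rms / pulse_band_rms
      mix[span] <- mix[span] + pulse_proto * gain
      all_ann[[length(all_ann) + 1]] <- song$annotations[k, , drop = FALSE]
      manifest[[length(manifest) + 1]] <-
        data.frame(song = si, note = k, begin_s = b, snr_db = song$snr_db[k])
      spans <- rbind(spans, c(b, b + entry$spec$pulse$duration_s))
    }
  }
  ann <- if (length(all_ann)) do.call(rbind, all_ann) else
    note_annotations(numeric(0), numeric(0))
  if (nrow(ann)) {
    ann <- ann[order(ann$begin_s), , drop = FALSE]
    ann$source_id <- paste0("soundscape_seed", spec$seed)
  }
  man <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(song = integer(0), note = integer(0), begin_s = numeric(0),
               snr_db = numeric(0))
  overlap <- FALSE
  if (nrow(spans) > 1) {
    o <- order(spans[, 1])
    overlap <- any(spans[o, 1][-1] < spans[o, 2][-nrow(spans)])
  }
  rec <- waveform_recording(mix, fs,
                            source_id = paste0("soundscape_seed", spec$seed))
  list(recording = rec, annotations = ann,
       manifest = list(notes = man, overlapping_songs = overlap,
                       seed = spec$seed, duration_s = spec$duration_s))
}
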