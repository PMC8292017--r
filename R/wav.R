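#' Read a single-channel WAV file
#'
#' Minimal RIFF/WAVE reader supporting PCM 16/24-bit and IEEE float 32-bit
#' encodings. Multi-channel files are reduced to the first channel with a
#' warning; amplitudes are returned as doubles in [-1, 1] for PCM input.
#'
#' @param path path to a `.wav` file.
#' @return a [waveform_recording()] with `source_id` set to the file name.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels   = readBin(raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate  = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      samples <- .decode_wav_data(con, size, fmt)
      if (size %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (fmt$n_channels > 1) {
    warning("multi-channel WAV; using first channel only: ", basename(path))
    samples <- samples[seq(1, length(samples), by = fmt$n_channels)]
  }
  waveform_recording(samples, fmt$sample_rate, source_id = basename(path))
}

.decode_wav_data <- function(con, size, fmt) {
  if (fmt$audio_format == 1 && fmt$bits == 16) {
    readBin(con, "integer", size / 2, 2, signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 1 && fmt$bits == 24) {
    raw <- readBin(con, "raw", size)
    n <- length(raw) / 3
    b1 <- as.integer(raw[seq(1, by = 3, length.out = n)])
    b2 <- as.integer(raw[seq(2, by = 3, length.out = n)])
    b3 <- as.integer(raw[seq(3, by = 3, length.out = n)])
    v <- b1 + 256 * b2 + 65536 * b3
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else if (fmt$audio_format == 3 && fmt$bits == 32) {
    readBin(con, "numeric", size / 4, 4, endian = "little")
  } else {
    stop("unsupported WAV encoding: format ", fmt$audio_format, ", ", fmt$bits, " bits")
  }
}

#' Write a waveform to a WAV file
#'
#' @param rec a [waveform_recording()] (or bare numeric vector plus `rate_hz`).
#' @param path output path.
#' @param rate_hz sampling rate, required when `rec` is a bare vector.
#' @param bits one of 32 (IEEE float, default, lossless for this package's
#'   pipelines) or 16 (PCM).
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, rate_hz = NULL, bits = 32) {
  if (inherits(rec, "waveform_recording")) {
    samples <- rec$samples
    rate_hz <- rec$sample_rate_hz
  } else {
    samples <- as.numeric(rec)
    if (is.null(rate_hz)) stop("rate_hz required for bare sample vectors")
  }
  stopifnot(bits %in% c(16, 32))
  n <- length(samples)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (bits == 32) 3 else 1), con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(round(rate_hz)), con, 4, endian = "little")
  writeBin(as.integer(round(rate_hz) * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 32) {
    writeBin(samples, con, 4, endian = "little")
  } else {
    v <- as.integer(pmax(-32768, pmin(32767, round(samples * 32768))))
    writeBin(v, con, 2, endian = "little")
  }
  invisible(path)
}
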