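#' Write a waveform to a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer for mono stimulus waveforms. Amplitudes are
#' expected in \[-1, 1\] and are scaled to the full signed 16-bit range;
#' values outside \[-1, 1\] are clipped with a warning.
#'
#' @param waveform numeric vector of samples (unitless amplitude).
#' @param sample_rate_hz sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, sample_rate_hz, path) {
  stopifnot(is.numeric(waveform), length(waveform) > 0,
            is.numeric(sample_rate_hz), sample_rate_hz > 0)
  if (any(abs(waveform) > 1)) {
    warning("waveform amplitudes outside [-1, 1] clipped")
    waveform <- pmax(-1, pmin(1, waveform))
  }
  samples <- as.integer(round(waveform * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(samples) * 2L
  sr <- as.integer(round(sample_rate_hz))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")     # byte rate
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(samples, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a WAV file
#'
#' Reads mono or multi-channel RIFF/WAVE files containing 16- or 24-bit PCM
#' or 32-bit IEEE float samples. Multi-channel files are averaged to mono.
#' Samples are returned as doubles scaled to \[-1, 1\].
#'
#' @param path file path.
#' @return list with `samples` (numeric vector) and `sample_rate_hz`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("cannot open WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, raw(), n = sz)
      u16 <- function(i) as.integer(fmt_raw[i]) + 256L * as.integer(fmt_raw[i + 1])
      u32 <- function(i) u16(i) + 65536 * u16(i + 2)
      fmt <- list(audio_format = u16(1), n_channels = u16(3),
                  sample_rate = u32(5), bits = u16(15))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, raw(), n = sz)
    } else {
      readBin(con, raw(), n = sz + sz %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data chunk): ", path)
  bits <- fmt$bits
  n_ch <- fmt$n_channels
  if (fmt$audio_format == 1 && bits == 16) {
    x <- readBin(data_raw, integer(), n = length(data_raw) / 2, size = 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 1 && bits == 24) {
    n <- length(data_raw) %/% 3
    b <- matrix(as.integer(data_raw[seq_len(3 * n)]), nrow = 3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else if (fmt$audio_format == 3 && bits == 32) {
    x <- readBin(data_raw, numeric(), n = length(data_raw) / 4, size = 4,
                 endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$audio_format, ", ",
         bits, "-bit)")
  }
  if (n_ch > 1) x <- rowMeans(matrix(x, ncol = n_ch, byrow = TRUE))
  list(samples = x, sample_rate_hz = fmt$sample_rate)
}
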