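#' Read a mono PCM WAV file
#'
#' Minimal reader for uncompressed PCM WAV (8/16/32-bit integer or 32-bit
#' float), returning samples scaled to `[-1, 1]`. Multi-channel files are
#' mixed down by averaging.
#'
#' @param path Path to a `.wav` file.
#' @return Numeric vector with attribute `fs` (sampling rate in Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (riff != "RIFF") stop("not a RIFF/WAV file", call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 4, useBytes = TRUE) != "WAVE")
    stop("not a WAV file", call. = FALSE)
  fmt <- NULL; data <- NULL
  while (is.null(data)) {
    id <- readChar(con, 4, useBytes = TRUE)
    if (!nzchar(id)) stop("malformed WAV: no data chunk", call. = FALSE)
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        format = sum(as.integer(raw[1:2]) * c(1, 256)),
        channels = sum(as.integer(raw[3:4]) * c(1, 256)),
        fs = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      n <- size / (fmt$bits / 8)
      data <- if (fmt$format == 3) {
        readBin(con, "numeric", n, 4, endian = "little")
      } else if (fmt$bits == 8) {
        (readBin(con, "integer", n, 1, signed = FALSE) - 128) / 128
      } else {
        readBin(con, "integer", n, fmt$bits / 8, signed = TRUE,
                endian = "little") / 2^(fmt$bits - 1)
      }
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
  if (fmt$channels > 1) {
    m <- matrix(data, nrow = fmt$channels)
    data <- colMeans(m)
  }
  attr(data, "fs") <- fmt$fs
  data
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param x Samples in `[-1, 1]` (clipped otherwise).
#' @param path Output path.
#' @param fs Sampling rate in Hz (default 1000, the model rate).
#' @return The path, invisibly.
#' @export
write_wav <- function(x, path, fs = 1000) {
  x <- pmin(pmax(as.numeric(x), -1), 1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")          # PCM, mono
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * 2), con, 4, endian = "little") # byte rate
  writeBin(c(2L, 16L), con, 2, endian = "little")         # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

#' Resample audio to the model rate
#'
#' Anti-aliased polyphase resampling (via [signal::resample()]) from an
#' arbitrary rate to the model's 1000 Hz.
#'
#' @param x Samples with attribute `fs`, or plain numeric plus `from_fs`.
#' @param from_fs Input rate in Hz (taken from `attr(x, "fs")` if absent).
#' @param to_fs Target rate (default 1000).
#' @return Numeric vector with attribute `fs = to_fs`.
#' @export
resample_audio <- function(x, from_fs = attr(x, "fs"), to_fs = 1000) {
  if (is.null(from_fs)) stop("input sampling rate unknown", call. = FALSE)
  if (from_fs == to_fs) { attr(x, "fs") <- to_fs; return(x) }
  r <- gcd_int(round(from_fs), round(to_fs))
  out <- signal::resample(as.numeric(x), p = round(to_fs) / r,
                          q = round(from_fs) / r)
  attr(out, "fs") <- to_fs
  out
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Write recordings to CSV
#'
#' Long-form CSV with columns `time_ms`, `electrode_id`, `value`.
#'
#' @param run A `wl_run` with electrode recordings.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_recordings_csv <- function(run, path) {
  utils::write.csv(recordings_df(run), path, row.names = FALSE)
  invisible(path)
}

#' Write a dispersion table to CSV
#' @param params,shape Passed to [dispersion()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dispersion_csv <- function(params, shape, path) {
  d <- dispersion(params, shape)
  utils::write.csv(
    d[, c("kx_index", "ky_index", "mu", "lambda", "omega_rad_per_step",
          "freq_hz")], path, row.names = FALSE)
  invisible(path)
}
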