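# Minimal RIFF/WAVE reader and writer. PCM 16/24/32-bit and IEEE float 32
# are supported, which covers the fixtures and typical recordings this
# package consumes. Samples are exchanged as doubles in [-1, 1].

#' Read a WAV file
#'
#' @param path file path.
#' @return list with `samples` (numeric matrix `[n x channels]`, in
#'   `[-1, 1]`) and `fs` (sample rate in Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  abort_if(!identical(riff, "RIFF"), "not a RIFF/WAVE file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  abort_if(!identical(wave, "WAVE"), "not a RIFF/WAVE file")
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little", signed = FALSE),
        n_channels   = readBin(raw[3:4], "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(raw[15:16], "integer", 1, 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  abort_if(is.null(fmt) || is.null(data_raw), "malformed WAV: missing fmt or data chunk")
  bytes <- fmt$bits / 8
  n_total <- length(data_raw) %/% (bytes * fmt$n_channels) * fmt$n_channels
  if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "numeric", n_total, 4, endian = "little")
  } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n_total, 2, signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 32L) {
    x <- readBin(data_raw, "integer", n_total, 4, endian = "little") / 2147483648
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw[seq_len(n_total * 3)]), nrow = 3)
    v <- m[1, ] + m[2, ] * 256L + m[3, ] * 65536L
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else {
    stop("unsupported WAV encoding (format ", fmt$audio_format, ", ",
         fmt$bits, " bits)", call. = FALSE)
  }
  samples <- matrix(x, ncol = fmt$n_channels, byrow = TRUE)
  list(samples = samples, fs = fmt$sample_rate)
}

#' Write a WAV file (IEEE float 32)
#'
#' Values with magnitude above 1 are written as-is but a warning is issued.
#'
#' @param samples numeric vector (mono) or matrix `[n x channels]`.
#' @param fs sample rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (max(abs(samples)) > 1) {
    warning("clipped samples: |x| > 1 written to ", path, call. = FALSE)
  }
  n_ch <- ncol(samples)
  interleaved <- as.numeric(t(samples))
  data_bytes <- length(interleaved) * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(3L, con, 2, endian = "little")            # IEEE float
  writeBin(as.integer(n_ch), con, 2, endian = "little")
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * n_ch * 4L), con, 4, endian = "little")
  writeBin(as.integer(n_ch * 4L), con, 2, endian = "little")
  writeBin(32L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, 4, endian = "little")
  writeBin(interleaved, con, 4, endian = "little")
  invisible(path)
}
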