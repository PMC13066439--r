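# Minimal 16-bit PCM mono RIFF/WAVE reader and writer (little-endian).

#' Write a waveform as a 16-bit PCM WAV file
#'
#' @param x Numeric samples in `[-1, 1]` full scale. Values outside the range
#'   are an error (clipping must be resolved upstream, not hidden here).
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".wav")
#' write_tone_wav(sin(2 * pi * 440 * (0:479) / 48000) * 0.5, f)
#' read_tone_wav(f)$sample_rate
write_tone_wav <- function(x, path, sample_rate = 48000) {
  if (any(!is.finite(x))) stop("waveform contains non-finite samples")
  if (max(abs(x)) > 1)
    stop(sprintf("samples exceed full scale (peak %.3f); refusing to clip",
                 max(abs(x))))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_bytes, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")              # block align
  writeBin(16L, con, size = 2, endian = "little")             # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Counterpart of [write_tone_wav()]; supports only the format that function
#' writes (PCM, mono, 16-bit).
#'
#' @param path File path.
#' @return List with `samples` (numeric in `[-1, 1]`), `sample_rate`,
#'   `n_channels` and `bits`.
#' @export
read_tone_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  sample_rate <- NULL; n_channels <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), 2, size = 2, endian = "little")
      n_channels <- fmt[2]
      sample_rate <- readBin(con, integer(), 1, size = 4, endian = "little")
      invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
      invisible(readBin(con, integer(), 1, size = 2, endian = "little"))
      bits <- readBin(con, integer(), 1, size = 2, endian = "little")
      if (fmt[1] != 1L || n_channels != 1L || bits != 16L)
        stop("only 16-bit PCM mono WAV is supported")
      skip <- size - 16L
      if (skip > 0) invisible(readBin(con, raw(), skip))
    } else if (id == "data") {
      samples <- readBin(con, integer(), size / 2, size = 2,
                         endian = "little", signed = TRUE) / 32767
      break
    } else {
      invisible(readBin(con, raw(), size))
    }
  }
  if (is.null(samples)) stop("no data chunk found")
  list(samples = samples, sample_rate = sample_rate,
       n_channels = n_channels, bits = bits)
}
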