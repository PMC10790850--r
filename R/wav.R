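#' Minimal 16-bit PCM WAV input/output
#'
#' Reads and writes canonical RIFF/WAVE files with 16-bit PCM samples, the
#' only flavor the pipeline produces. Samples are represented in R as a
#' samples-by-channels matrix in [-1, 1]; writing quantizes to 16 bits
#' (round-trip error bounded by 2^-15).
#'
#' @param path file path.
#' @return `read_wav` returns `list(waveform, srate_hz)` with `waveform` a
#'   samples x channels matrix in [-1, 1].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_fmt("'%s' is not a RIFF file", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_fmt("'%s' is not a WAVE file", path)
  srate <- NULL; n_chan <- NULL; bits <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", size / 2, 2, endian = "little",
                     signed = FALSE)
      n_chan <- fmt[2]
      srate <- fmt[3] + 65536 * fmt[4]
      bits <- fmt[8]
      if (fmt[1] != 1 || bits != 16)
        stop_fmt("only 16-bit PCM WAV supported")
    } else if (identical(id, "data")) {
      data <- readBin(con, "integer", size / 2, 2, endian = "little",
                      signed = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(data) || is.null(srate)) stop_fmt("malformed WAV '%s'", path)
  wf <- matrix(data / 32768, ncol = n_chan, byrow = TRUE)
  list(waveform = wf, srate_hz = srate)
}

#' @rdname read_wav
#' @param waveform samples x channels numeric matrix in [-1, 1].
#' @param srate_hz sampling rate (Hz).
#' @export
write_wav <- function(waveform, srate_hz, path) {
  waveform <- as.matrix(waveform)
  if (max(abs(waveform)) > 1 + 1e-9) stop_fmt("waveform exceeds [-1, 1]")
  n_chan <- ncol(waveform)
  pcm <- as.integer(pmax(-32768, pmin(32767, round(t(waveform) * 32767))))
  data_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(as.integer(n_chan), con, size = 2, endian = "little")
  writeBin(as.integer(srate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(srate_hz * n_chan * 2), con, size = 4, endian = "little")
  writeBin(as.integer(n_chan * 2), con, size = 2, endian = "little") # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
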