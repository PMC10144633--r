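# Minimal RIFF/WAVE I/O for 16-bit PCM mono clips -- the one exchange
# format the vocal pipeline reads and writes.

#' Write an audio clip as 16-bit PCM mono WAV
#'
#' @param clip an `audio_clip` (samples in [-1, 1]).
#' @param path output file.
#' @export
write_wav <- function(clip, path) {
  samples <- clamp(clip$samples, -1, 1)
  pcm <- as.integer(round(samples * 32767))
  sr <- as.integer(clip$sample_rate)
  data_size <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' Mono files are returned as-is; stereo input is down-mixed to mono
#' with a warning.
#'
#' @param path WAV file.
#' @return an `audio_clip`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop_invalid("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF"))
    stop_invalid(path, " is not a RIFF file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE"))
    stop_invalid(path, " is not a WAVE file")
  sr <- NULL; n_channels <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop_invalid("only PCM WAV is supported")
      n_channels <- fmt[2]
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      ba_bits <- readBin(con, "integer", 2, size = 2, endian = "little")
      bits <- ba_bits[2]
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (id == "data") {
      if (is.null(bits)) stop_invalid("data chunk before fmt chunk")
      if (bits != 16L) stop_invalid("only 16-bit PCM is supported")
      samples <- readBin(con, "integer", size / 2, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(samples)) stop_invalid("no data chunk in ", path)
  x <- samples / 32767
  if (n_channels == 2L) {
    warning("stereo WAV down-mixed to mono")
    x <- (x[c(TRUE, FALSE)] + x[c(FALSE, TRUE)]) / 2
  } else if (n_channels != 1L) {
    stop_invalid("unsupported channel count: ", n_channels)
  }
  audio_clip(x, sr)
}
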