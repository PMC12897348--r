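#' Read a mono PCM-16 WAV file
#'
#' Minimal RIFF/WAVE reader for the 16-bit mono PCM files this package
#' writes. Samples are returned scaled to `[-1, 1]`.
#'
#' @param path file path
#' @param route route tag to attach (`"nose"` or `"mouth"`)
#' @return A [BreathRecording-class].
#' @export
readWav <- function(path, route = "nose") {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (!nzchar(id)) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      channels <- fmt[2]
      rate <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 2, endian = "little"))
      bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size / 2, 2, endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(rate) || is.null(samples)) stop("malformed WAV: ", path)
  if (!identical(channels, 1L) || !identical(bits, 16L))
    stop("only mono PCM-16 supported")
  BreathRecording(samples / 32767, rate, route)
}

#' Write a recording as mono PCM-16 WAV
#'
#' Samples are clipped to `[-1, 1]` and quantized to 16 bits.
#'
#' @param recording a [BreathRecording-class]
#' @param path output file path
#' @return `path`, invisibly.
#' @export
writeWav <- function(recording, path) {
  x <- pmin(1, pmax(-1, recording@samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, 4, endian = "little")
  writeBin(as.integer(c(1, 1)), con, 2, endian = "little")       # PCM, mono
  writeBin(as.integer(recording@rate), con, 4, endian = "little")
  writeBin(as.integer(recording@rate * 2), con, 4, endian = "little")
  writeBin(as.integer(c(2, 16)), con, 2, endian = "little")      # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
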