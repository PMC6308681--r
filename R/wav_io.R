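# Minimal RIFF/WAVE I/O: 16-bit PCM little-endian stereo.

#' Write a stereo buffer to a WAV file
#'
#' Standard RIFF/WAVE container, PCM 16-bit little-endian, two channels.
#' Samples are clipped to \[-1, 1\] and quantized to int16.
#'
#' @param buffer A `"stereo_buffer"` (see [render_cycle()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(buffer, path) {
  stopifnot(inherits(buffer, "stereo_buffer"))
  n <- length(buffer$left)
  if (length(buffer$right) != n) stop("channel lengths differ", call. = FALSE)
  rate <- as.integer(buffer$sample_rate)
  inter <- as.vector(rbind(pmin(1, pmax(-1, buffer$left)),
                           pmin(1, pmax(-1, buffer$right))))
  pcm <- as.integer(round(inter * 32767))
  data_bytes <- 4L * n  # 2 channels x 2 bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_bytes, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")      # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")       # PCM
  writeBin(2L, con, size = 2, endian = "little")       # channels
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 4L, con, size = 4, endian = "little") # byte rate
  writeBin(4L, con, size = 2, endian = "little")       # block align
  writeBin(16L, con, size = 2, endian = "little")      # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM stereo WAV file back into a stereo buffer
#'
#' @param path Path to a WAV file written by [write_wav()] (or any
#'   16-bit PCM stereo RIFF file).
#' @return A `"stereo_buffer"` with samples in \[-1, 1\].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4, useBytes = TRUE), "RIFF")) {
    stop("not a RIFF file: ", path, call. = FALSE)
  }
  readBin(con, "integer", size = 4, endian = "little")
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    stop("not a WAVE file: ", path, call. = FALSE)
  }
  rate <- NULL; channels <- NULL; bits <- NULL; pcm <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV is supported", call. = FALSE)
      channels <- fmt[2]
      rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      ba_bits <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      bits <- ba_bits[2]
      if (size > 16) readBin(con, "raw", n = size - 16L)
    } else if (id == "data") {
      pcm <- readBin(con, "integer", n = size %/% 2L, size = 2,
                     endian = "little")
    } else {
      readBin(con, "raw", n = size)
    }
    if (!is.null(pcm) && !is.null(rate)) break
  }
  if (is.null(pcm) || is.null(rate)) stop("malformed WAV file", call. = FALSE)
  if (bits != 16L || channels != 2L) {
    stop("expected 16-bit stereo PCM", call. = FALSE)
  }
  structure(list(left = pcm[seq(1, length(pcm), by = 2)] / 32767,
                 right = pcm[seq(2, length(pcm), by = 2)] / 32767,
                 sample_rate = rate),
            class = "stereo_buffer")
}
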