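# Raw depth frame container and 16-bit PGM I/O.

#' Construct a raw depth frame
#'
#' A frame is a height x width integer matrix of 11-bit raw depth
#' readings (row 1 = top of the image, column 1 = left). The value 2047
#' is the sensor's invalid-reading sentinel and never denotes a measured
#' distance.
#'
#' @param values Integer matrix (height rows x width columns) with values
#'   in \[0, 2047\].
#' @return An object of class `"raw_depth_frame"`.
#' @export
raw_depth_frame <- function(values) {
  if (!is.matrix(values)) stop("values must be a matrix", call. = FALSE)
  .check_raw(values)
  structure(list(values = matrix(as.integer(values), nrow(values), ncol(values)),
                 width = ncol(values), height = nrow(values)),
            class = "raw_depth_frame")
}

#' @export
print.raw_depth_frame <- function(x, ...) {
  nvalid <- sum(x$values != RAW_INVALID)
  cat("<raw_depth_frame>", x$width, "x", x$height, "px,",
      nvalid, "valid readings\n")
  invisible(x)
}

#' Read a raw depth frame from a 16-bit binary PGM file
#'
#' Frames are stored as plain `P5` PGM with maxval 65535 (two bytes per
#' pixel, most significant byte first, rows top to bottom). Pixels
#' outside the 11-bit range \[0, 2047\] are rejected.
#'
#' @param path Path to a PGM file.
#' @return A [raw_depth_frame()].
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2, useBytes = TRUE)
  if (!identical(magic, "P5")) stop("not a binary (P5) PGM file: ", path,
                                    call. = FALSE)
  tokens <- integer(0)
  # header: width, height, maxval; '#' comments allowed, any whitespace
  while (length(tokens) < 3) {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0) stop("truncated PGM header", call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (length(ch) == 0 || ch == "\n") break
      }
    } else if (grepl("[0-9]", ch)) {
      num <- ch
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (length(ch) == 0 || !grepl("[0-9]", ch)) break
        num <- paste0(num, ch)
      }
      tokens <- c(tokens, as.integer(num))
    }
  }
  width <- tokens[1]; height <- tokens[2]; maxval <- tokens[3]
  if (maxval < 256 || maxval > 65535) {
    stop("expected a 16-bit PGM (maxval in [256, 65535]), got maxval ",
         maxval, call. = FALSE)
  }
  n <- width * height
  bytes <- readBin(con, "integer", n = 2 * n, size = 1, signed = FALSE)
  if (length(bytes) < 2 * n) stop("truncated PGM pixel data", call. = FALSE)
  vals <- bytes[seq(1, 2 * n, by = 2)] * 256L + bytes[seq(2, 2 * n, by = 2)]
  if (any(vals > RAW_MAX)) {
    stop("PGM contains values outside the 11-bit raw range [0, 2047]",
         call. = FALSE)
  }
  raw_depth_frame(matrix(vals, nrow = height, ncol = width, byrow = TRUE))
}

#' Write a raw depth frame as a 16-bit binary PGM file
#'
#' @param frame A [raw_depth_frame()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(frame, path) {
  stopifnot(inherits(frame, "raw_depth_frame"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n65535\n", frame$width, frame$height), con,
            eos = NULL)
  vals <- as.integer(t(frame$values))  # row-major, top to bottom
  bytes <- as.raw(rbind(vals %/% 256L, vals %% 256L))
  writeBin(bytes, con)
  invisible(path)
}
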