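# Small-field grid: partition a depth frame into rows x cols blocks and
# reduce each block to one 8-bit volume code.

#' Configure the small-field grid
#'
#' The frame is tiled into `rows x cols` contiguous rectangular blocks
#' ("small fields"); the default 6 x 5 grid turns a 640 x 480 frame into
#' 30 fields of 128 x 80 pixels. Each field is reduced to one volume
#' code, with a near-obstacle override: if the closest reading in a field
#' is nearer than `near_limit` metres, the field takes the code of that
#' minimum reading rather than the field average, so nearby obstacles are
#' never diluted by far background.
#'
#' @param rows,cols Grid dimensions (defaults 6 rows x 5 columns).
#' @param near_limit Near-obstacle override distance in metres
#'   (default 1.2).
#' @param near_limit_raw The same limit in raw sensor units; derived from
#'   `near_limit` through the sensor calibration (default 801) when not
#'   given. The comparison is done in raw units since the transfer
#'   functions are monotone.
#' @param method `"averaged"` for the four-step aggregation (lookup, sum
#'   valid codes, average unless a near obstacle is present) or
#'   `"min_only"` to always take the code of the minimum reading.
#' @param sensor Sensor model used to derive `near_limit_raw`.
#' @return An object of class `"grid_config"`.
#' @export
grid_config <- function(rows = 6L, cols = 5L, near_limit = 1.2,
                        near_limit_raw = NULL, method = c("averaged", "min_only"),
                        sensor = sensor_model()) {
  method <- match.arg(method)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("rows and cols must be >= 1", call. = FALSE)
  if (is.null(near_limit_raw)) {
    near_limit_raw <- metric_to_raw(near_limit, sensor)
  }
  near_limit_raw <- as.integer(near_limit_raw)
  if (near_limit_raw <= RAW_MIN_VALID || near_limit_raw >= RAW_INVALID) {
    stop("near_limit_raw must lie in (488, 2047)", call. = FALSE)
  }
  structure(list(rows = rows, cols = cols, near_limit = near_limit,
                 near_limit_raw = near_limit_raw, method = method),
            class = "grid_config")
}

#' Partition a frame into small-field pixel blocks
#'
#' Splits the frame into `rows x cols` contiguous, non-overlapping
#' rectangles that exactly tile it. Frame dimensions must be divisible by
#' the grid dimensions.
#'
#' @param frame A [raw_depth_frame()].
#' @param config A [grid_config()].
#' @return A `rows x cols` list-matrix of integer pixel matrices; element
#'   `[r, c]` is the block for grid row `r` (top) and column `c` (left).
#' @export
partition <- function(frame, config) {
  stopifnot(inherits(frame, "raw_depth_frame"), inherits(config, "grid_config"))
  if (frame$height %% config$rows != 0L || frame$width %% config$cols != 0L) {
    stop("frame dimensions (", frame$width, "x", frame$height,
         ") are not divisible by the grid (", config$cols, "x", config$rows,
         ")", call. = FALSE)
  }
  bh <- frame$height %/% config$rows
  bw <- frame$width %/% config$cols
  blocks <- matrix(vector("list", config$rows * config$cols),
                   nrow = config$rows, ncol = config$cols)
  for (r in seq_len(config$rows)) {
    for (c in seq_len(config$cols)) {
      blocks[[r, c]] <- frame$values[((r - 1L) * bh + 1L):(r * bh),
                                     ((c - 1L) * bw + 1L):(c * bw),
                                     drop = FALSE]
    }
  }
  blocks
}

#' Reduce one pixel block to a volume code
#'
#' Averaged method: (1) every pixel is converted through the lookup
#' table; (2) pixels carrying the invalid sentinel 2047 are discarded,
#' the remaining codes are summed and counted and the minimum raw reading
#' is tracked; (3) if that minimum is farther than the near limit and at
#' least one pixel was valid, the field code is the rounded mean of the
#' valid codes; (4) otherwise (a near obstacle) the field takes the code
#' of the minimum reading. A field with no valid pixel is silent (255).
#' The mean is taken over real-valued (unrounded) codes to avoid double
#' rounding. Min-only method: the code of the minimum valid reading.
#'
#' @param block Integer matrix (or vector) of raw readings.
#' @param lut A [build_lookup_table()] result.
#' @param config A [grid_config()].
#' @return A single integer volume code in \[0, 255\].
#' @export
aggregate_field <- function(block, lut, config) {
  raw <- as.integer(block)
  if (length(raw) == 0L) stop("empty pixel block", call. = FALSE)
  valid <- raw != RAW_INVALID
  if (!any(valid)) return(CODE_SILENCE)
  vraw <- raw[valid]
  min_raw <- min(vraw)
  if (config$method == "min_only") return(lut$entries[min_raw + 1L])
  if (min_raw > config$near_limit_raw) {
    as.integer(round_half_away(mean(lut$levels[vraw + 1L])))
  } else {
    lut$entries[min_raw + 1L]
  }
}

#' Map a full frame to its small-field grid of volume codes
#'
#' @param frame A [raw_depth_frame()].
#' @param lut A [build_lookup_table()] result.
#' @param config A [grid_config()].
#' @return An object of class `"small_field_grid"` with integer matrices
#'   `codes` and `valid_counts` (rows x cols, row 1 = top).
#' @export
map_frame <- function(frame, lut, config = grid_config()) {
  blocks <- partition(frame, config)
  codes <- matrix(0L, config$rows, config$cols)
  counts <- matrix(0L, config$rows, config$cols)
  for (r in seq_len(config$rows)) {
    for (c in seq_len(config$cols)) {
      codes[r, c] <- aggregate_field(blocks[[r, c]], lut, config)
      counts[r, c] <- sum(blocks[[r, c]] != RAW_INVALID)
    }
  }
  structure(list(codes = codes, valid_counts = counts, config = config),
            class = "small_field_grid")
}

#' @export
print.small_field_grid <- function(x, ...) {
  cat("<small_field_grid>", x$config$rows, "x", x$config$cols,
      "volume codes (0 = loudest, 255 = silence)\n")
  print(x$codes)
  invisible(x)
}

#' Write a small-field grid as CSV
#'
#' Rows top to bottom, comma-separated volume codes, no header.
#'
#' @param grid A `"small_field_grid"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "small_field_grid"))
  write.table(grid$codes, path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a small-field grid back from CSV
#'
#' Intended for renderer-only workflows; per-field valid-pixel counts are
#' not persisted and come back as `NA`.
#'
#' @param path CSV path written by [write_grid_csv()].
#' @param config Optional [grid_config()]; defaults to one matching the
#'   CSV dimensions.
#' @return A `"small_field_grid"`.
#' @export
read_grid_csv <- function(path, config = NULL) {
  codes <- as.matrix(read.table(path, sep = ",", header = FALSE))
  dimnames(codes) <- NULL
  if (any(codes < 0) || any(codes > 255) || any(codes != trunc(codes))) {
    stop("grid CSV must contain integer codes in [0, 255]", call. = FALSE)
  }
  if (is.null(config)) {
    config <- grid_config(rows = nrow(codes), cols = ncol(codes))
  }
  structure(list(codes = matrix(as.integer(codes), nrow(codes), ncol(codes)),
                 valid_counts = matrix(NA_integer_, nrow(codes), ncol(codes)),
                 config = config),
            class = "small_field_grid")
}
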