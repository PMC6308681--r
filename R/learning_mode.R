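# Learning mode: a single-tone obstacle indicator whose pitch follows
# head inclination, used to train the row-height <-> tone-height mapping.

#' Learning-mode configuration
#'
#' In learning mode the device reads the minimum distance in the central
#' small field at 20 Hz (every 50 ms) and plays a single tone: its
#' loudness follows the same distance transform as normal mode and its
#' pitch is the row-tone selected by the sensor's tilt. Tilt bins span
#' the vertical field of view (43 degrees, so ~7.17 degrees per row over
#' six rows); beyond +/-21.5 degrees no sound plays. Every 80 readings
#' (4 s) the 100 Hz reference is replayed, 300 ms long with 200 ms
#' pauses around it.
#'
#' @param refresh_ms Reading period in ms (default 50, i.e. 20 Hz).
#' @param reference_every Insert the reference pattern every N readings
#'   (default 80).
#' @param reference_ms,pause_ms Reference-tone and surrounding-pause
#'   durations in ms (defaults 300 and 200).
#' @param vfov Vertical field of view in degrees (default 43).
#' @param rows Number of tilt bins / grid rows (default 6).
#' @param tilt_resolution Accelerometer resolution in degrees
#'   (default 0.5).
#' @return An object of class `"learning_config"`.
#' @export
learning_config <- function(refresh_ms = 50, reference_every = 80L,
                            reference_ms = 300, pause_ms = 200,
                            vfov = 43, rows = 6L, tilt_resolution = 0.5) {
  if (refresh_ms <= 0) stop("refresh_ms must be > 0", call. = FALSE)
  if (reference_every < 1) stop("reference_every must be >= 1", call. = FALSE)
  structure(list(refresh_ms = refresh_ms,
                 reference_every = as.integer(reference_every),
                 reference_ms = reference_ms, pause_ms = pause_ms,
                 vfov = vfov, rows = as.integer(rows),
                 tilt_resolution = tilt_resolution),
            class = "learning_config")
}

#' Map a tilt angle to a grid row (tone) index
#'
#' The vertical field of view is split into `rows` equal bins of
#' `vfov / rows` degrees (~7.17 at the defaults). Tilt straight up by
#' more than `vfov / 2` (21.5 degrees) — or equally far down — selects no
#' row and produces silence. Bins are upper-edge inclusive; the lowest
#' bin also includes its lower edge so the full range (-21.5, +21.5\]
#' plus the -21.5 boundary is covered. Row 0 is the top bin (highest
#' tone).
#'
#' @param angle Tilt in degrees, positive = up. The accelerometer
#'   quantizes to 0.5-degree steps; any real angle is accepted.
#' @param config A [learning_config()].
#' @return Integer row index in `0:(rows-1)`, or `NA` for out-of-range
#'   tilt.
#' @export
tilt_to_row <- function(angle, config = learning_config()) {
  half <- config$vfov / 2
  bin <- config$vfov / config$rows
  out <- rep(NA_integer_, length(angle))
  ok <- abs(angle) <= half
  x <- half - angle[ok]               # 0 at full tilt up, vfov at full down
  row <- pmin(config$rows - 1L, as.integer(floor(x / bin)))
  out[ok] <- row
  out
}

#' Extract the central small field of a frame
#'
#' The learning mode watches only the obstacle straight ahead: a block
#' of one small-field size (width/cols x height/rows) centred on the
#' frame centre.
#'
#' @param frame A [raw_depth_frame()].
#' @param cols,rows Grid dimensions used for the field size (defaults
#'   5 and 6).
#' @return Integer matrix of raw readings.
#' @export
central_region <- function(frame, cols = 5L, rows = 6L) {
  stopifnot(inherits(frame, "raw_depth_frame"))
  if (frame$width %% cols != 0L || frame$height %% rows != 0L) {
    stop("frame dimensions must be divisible by the grid dimensions",
         call. = FALSE)
  }
  bw <- frame$width %/% cols
  bh <- frame$height %/% rows
  x0 <- (frame$width - bw) %/% 2L
  y0 <- (frame$height - bh) %/% 2L
  frame$values[(y0 + 1L):(y0 + bh), (x0 + 1L):(x0 + bw), drop = FALSE]
}

#' One learning-mode reading: tilt + frame -> tone event
#'
#' The volume code is the normal-mode transform of the minimum valid
#' reading in the central region (255 if none is valid); the frequency is
#' the bank tone of the tilt-selected row, or silence when the tilt is
#' out of range.
#'
#' @param frame A [raw_depth_frame()].
#' @param tilt Tilt angle in degrees.
#' @param lut A [build_lookup_table()] result (shared with normal mode).
#' @param bank A [default_tone_bank()].
#' @param config A [learning_config()].
#' @return List with `frequency` (Hz or `NA` for silence), `gain_db`,
#'   `code` and `row`.
#' @export
learning_step <- function(frame, tilt, lut, bank = default_tone_bank(),
                          config = learning_config()) {
  region <- central_region(frame, rows = config$rows)
  valid <- region[region != RAW_INVALID]
  code <- if (length(valid)) lut$entries[min(valid) + 1L] else CODE_SILENCE
  row <- tilt_to_row(tilt, config)
  if (is.na(row)) {
    return(list(frequency = NA_real_, gain_db = NA_real_, code = code,
                row = NA_integer_))
  }
  tone <- bank$tones[bank$tones$row == row, , drop = FALSE]
  list(frequency = tone$freq_hz, gain_db = tone$gain_db, code = code,
       row = row)
}

#' Render a learning-mode session to audio
#'
#' One centred (unpanned) tone segment per reading, `refresh_ms` long;
#' every `reference_every`-th reading is replaced by the reference
#' pattern: a pause, the 300 ms reference tone, and another pause.
#'
#' @param frames A single [raw_depth_frame()] (reused for every reading)
#'   or a list of frames, one per reading.
#' @param tilts Numeric vector of tilt angles, one per reading.
#' @param lut A [build_lookup_table()] result.
#' @param bank A [default_tone_bank()].
#' @param config A [learning_config()].
#' @param audio An [audio_config()].
#' @return A `"stereo_buffer"`; attribute `"n_references"` counts the
#'   inserted reference patterns.
#' @export
render_learning_session <- function(frames, tilts, lut,
                                    bank = default_tone_bank(),
                                    config = learning_config(),
                                    audio = audio_config()) {
  if (inherits(frames, "raw_depth_frame")) {
    frames <- rep(list(frames), length(tilts))
  }
  if (length(frames) != length(tilts)) {
    stop("frames and tilts must have equal length", call. = FALSE)
  }
  if (length(tilts) == 0L) stop("no readings given", call. = FALSE)
  rate <- audio$sample_rate
  center <- pan_gains(0)
  nref <- 0L
  parts <- vector("list", length(tilts))
  for (i in seq_along(tilts)) {
    if (i %% config$reference_every == 0L) {
      nref <- nref + 1L
      npause <- round(config$pause_ms * rate / 1000)
      ref <- synthesize_tone(bank$reference_freq, config$reference_ms,
                             bank$reference_gain_db, bank, audio)
      ref <- ref * .fade_envelope(length(ref), rate)
      mono <- c(numeric(npause), ref, numeric(npause))
    } else {
      step <- learning_step(frames[[i]], tilts[i], lut, bank, config)
      n <- round(config$refresh_ms * rate / 1000)
      if (is.na(step$frequency) || step$code == CODE_SILENCE) {
        mono <- numeric(n)
      } else {
        a <- volume_gain(step$code)
        mono <- a * synthesize_tone(step$frequency, config$refresh_ms,
                                    step$gain_db, bank, audio)
        mono <- mono * .fade_envelope(n, rate)
      }
    }
    parts[[i]] <- mono
  }
  mono <- unlist(parts)
  structure(list(left = center[["left"]] * mono,
                 right = center[["right"]] * mono,
                 sample_rate = rate),
            class = "stereo_buffer", n_references = nref)
}
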