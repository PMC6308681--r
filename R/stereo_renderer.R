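# Offline audio synthesis of one sonification cycle: per-slot tone
# mixing, distance-to-amplitude mapping, column panning.

#' Audio output configuration
#'
#' @param sample_rate Samples per second (44100 default; the embedded
#'   device alternative is 22050; other positive rates are accepted).
#' @param hfov Horizontal field of view in degrees, used to spread the
#'   grid columns across the stereo stage (default 57).
#' @return An object of class `"audio_config"` (bit depth is fixed at
#'   16-bit PCM for WAV output).
#' @export
audio_config <- function(sample_rate = 44100, hfov = 57) {
  if (sample_rate <= 0) stop("sample_rate must be > 0", call. = FALSE)
  if (hfov <= 0 || hfov >= 180) stop("hfov must be in (0, 180)", call. = FALSE)
  structure(list(sample_rate = sample_rate, bit_depth = 16L, hfov = hfov),
            class = "audio_config")
}

#' Amplitude factor of a volume code
#'
#' Codes run from 0 (nearest, loudest) to 255 (silence); the amplitude
#' factor is linear: `(255 - code) / 255`.
#'
#' @param code Integer volume code(s) in \[0, 255\].
#' @return Amplitude factor(s) in \[0, 1\].
#' @export
volume_gain <- function(code) {
  if (any(code < 0) || any(code > 255)) {
    stop("volume codes must lie in [0, 255]", call. = FALSE)
  }
  (255 - code) / 255
}

#' Azimuth of a grid column's angular sector
#'
#' The horizontal field of view is split evenly over the columns; a
#' column is panned to the centre angle of its sector. Negative = left.
#'
#' @param col 0-based column index.
#' @param ncols Number of columns.
#' @param hfov Horizontal field of view in degrees.
#' @return Azimuth in degrees.
#' @export
column_azimuth <- function(col, ncols, hfov) {
  if (any(col < 0) || any(col >= ncols)) {
    stop("col must satisfy 0 <= col < ncols", call. = FALSE)
  }
  -hfov / 2 + (col + 0.5) * hfov / ncols
}

#' Constant-power stereo pan gains
#'
#' Maps an azimuth in \[-90, 90\] degrees to left/right channel gains on
#' a quarter sine/cosine arc, so that `left^2 + right^2 = 1` at every
#' position (equal perceived power while the image moves).
#'
#' @param azimuth Azimuth in degrees; −90 = hard left, +90 = hard right.
#' @return Named numeric vector `c(left =, right =)`.
#' @export
pan_gains <- function(azimuth) {
  if (azimuth < -90 || azimuth > 90) {
    stop("azimuth must lie in [-90, 90] degrees", call. = FALSE)
  }
  theta <- (azimuth + 90) / 180 * (pi / 2)
  c(left = cos(theta), right = sin(theta))
}

# raised-cosine fade-in/out envelope over the first/last `fade_ms`
.fade_envelope <- function(n, rate, fade_ms = 5) {
  env <- rep(1, n)
  nf <- min(round(fade_ms * rate / 1000), n %/% 2)
  if (nf > 0) {
    ramp <- (1 - cos(pi * seq_len(nf) / nf)) / 2
    env[seq_len(nf)] <- ramp
    env[n - nf + seq_len(nf)] <- rev(ramp)
  }
  env
}

#' Synthesize one sine tone block
#'
#' A zero-phase sine of the requested duration; peak amplitude is the
#' bank's base amplitude scaled by the gain in dB. If the gained
#' amplitude would exceed full scale it is limited to 1 with a warning.
#'
#' @param frequency Hz.
#' @param duration_ms Duration in milliseconds.
#' @param gain_db Gain in dB relative to the base amplitude.
#' @param bank A [default_tone_bank()].
#' @param audio An [audio_config()].
#' @return Numeric vector of `round(duration_ms * rate / 1000)` mono
#'   samples.
#' @export
synthesize_tone <- function(frequency, duration_ms, gain_db, bank,
                            audio = audio_config()) {
  if (duration_ms <= 0) stop("duration must be > 0", call. = FALSE)
  rate <- audio$sample_rate
  n <- round(duration_ms * rate / 1000)
  amp <- bank$base_amplitude * 10^(gain_db / 20)
  if (!is.finite(amp)) amp <- 0
  if (amp > 1) {
    warning("gained amplitude ", signif(amp, 4), " exceeds full scale; limited to 1")
    amp <- 1
  }
  amp * sin(2 * pi * frequency * (seq_len(n) - 1) / rate)
}

# Internal: stereo samples for one schedule event.
.render_event <- function(event, grid, bank, audio) {
  rate <- audio$sample_rate
  n <- round(event$duration_ms * rate / 1000)
  if (event$kind == "pause") {
    return(list(left = numeric(n), right = numeric(n)))
  }
  if (event$kind == "reference") {
    mono <- synthesize_tone(bank$reference_freq, event$duration_ms,
                            bank$reference_gain_db, bank, audio)
    mono <- mono * .fade_envelope(n, rate)
    g <- pan_gains(0)
    return(list(left = g[["left"]] * mono, right = g[["right"]] * mono))
  }
  # scan_column: the scan's three tones in parallel, each scaled by its
  # cell's distance-derived amplitude
  tones <- bank$tones[bank$tones$scan == event$scan, , drop = FALSE]
  mono <- numeric(n)
  t <- (seq_len(n) - 1) / rate
  for (i in seq_len(nrow(tones))) {
    code <- grid$codes[tones$row[i] + 1L, event$col + 1L]
    a <- bank$base_amplitude * 10^(tones$gain_db[i] / 20) * volume_gain(code)
    if (a > 0) mono <- mono + a * sin(2 * pi * tones$freq_hz[i] * t)
  }
  mono <- mono * .fade_envelope(n, rate)
  g <- pan_gains(column_azimuth(event$col, grid$config$cols, audio$hfov))
  out <- list(left = g[["left"]] * mono, right = g[["right"]] * mono)
  peak <- max(abs(out$left), abs(out$right), 0)
  if (peak > 1) {
    warning("mixed slot peak ", signif(peak, 4), " exceeds full scale; rescaled")
    out$left <- out$left / peak
    out$right <- out$right / peak
  }
  out
}

#' Render one full sonification cycle to a stereo buffer
#'
#' Concatenates the schedule's events: the reference tone (centred, fixed
#' volume), pauses, and column slots in which the scan's three row-tones
#' play in parallel, each attenuated by its cell's volume code and the
#' whole slot panned to the column's azimuth. Slots are given 5 ms
#' raised-cosine fades to avoid clicks; a slot whose mixed peak exceeds
#' full scale is rescaled (with a warning) preserving relative levels.
#'
#' @param grid A `"small_field_grid"` whose rows/scans match the bank.
#' @param bank A [default_tone_bank()].
#' @param schedule A [build_schedule()] result.
#' @param audio An [audio_config()].
#' @return An object of class `"stereo_buffer"`: `left`, `right`
#'   (numeric samples in \[-1, 1\]) and `sample_rate`.
#' @export
render_cycle <- function(grid, bank = default_tone_bank(),
                         schedule = build_schedule(),
                         audio = audio_config()) {
  stopifnot(inherits(grid, "small_field_grid"))
  needed_rows <- max(bank$tones$row) + 1L
  if (grid$config$rows != needed_rows) {
    stop("grid has ", grid$config$rows, " rows but the tone bank encodes ",
         needed_rows, call. = FALSE)
  }
  ncols <- grid$config$cols
  if (any(schedule$col[!is.na(schedule$col)] >= ncols)) {
    stop("schedule addresses columns beyond the grid", call. = FALSE)
  }
  parts <- lapply(seq_len(nrow(schedule)), function(i) {
    .render_event(schedule[i, ], grid, bank, audio)
  })
  structure(list(left = unlist(lapply(parts, `[[`, "left")),
                 right = unlist(lapply(parts, `[[`, "right")),
                 sample_rate = audio$sample_rate),
            class = "stereo_buffer")
}

#' @export
print.stereo_buffer <- function(x, ...) {
  cat("<stereo_buffer>", length(x$left), "samples/channel @",
      x$sample_rate, "Hz (", round(length(x$left) / x$sample_rate, 3),
      "s )\n")
  invisible(x)
}
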