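# Tone bank and cycle schedule: which tone encodes which grid row, and
# when each grid column is played.

.note_semitones <- c(C = 0L, Cis = 1L, D = 2L, Dis = 3L, E = 4L, F = 5L,
                     Fis = 6L, G = 7L, Gis = 8L, A = 9L, Ais = 10L, B = 11L)

#' Equal-temperament frequency of a chord tone, with a cents shift
#'
#' Computes the frequency of a named note in a given octave under
#' twelve-tone equal temperament with A4 = 440 Hz, then applies a shift
#' in cents (1 cent = 1/1200 octave). The device's tones are C7-chord
#' notes (C, E, G, Ais) raised by 50 cents — a quarter tone — spread over
#' several octaves.
#'
#' @param chord_tone Note name (German convention: `"Ais"` = A-sharp).
#' @param octave Octave number, 0–9 (scientific pitch notation).
#' @param cents_shift Shift in cents (default 0); +50 is a quarter tone up.
#' @return Frequency in Hz, rounded to 2 decimals.
#' @examples
#' make_tone_frequency("C", 7, 50)   # 2154.33
#' make_tone_frequency("A", 4)       # 440
#' @export
make_tone_frequency <- function(chord_tone, octave, cents_shift = 0) {
  if (!chord_tone %in% names(.note_semitones)) {
    stop("unknown tone name: ", chord_tone, call. = FALSE)
  }
  if (octave < 0 || octave > 9) stop("octave must be in [0, 9]", call. = FALSE)
  s <- .note_semitones[[chord_tone]]
  f <- 440 * 2^((octave - 4) + (s - 9) / 12 + cents_shift / 1200)
  round(f, 2)
}

#' The device's six-tone bank
#'
#' Six fixed-frequency sine tones encode the six grid rows; within a scan
#' a higher row is a higher tone. The three highest tones (2154.33,
#' 806.97, 479.86 Hz) belong to the upper scan (grid rows 0–2, top
#' down) and the three lowest (403.49, 169.63, 67.32 Hz) to the lower
#' scan (rows 3–5). Per-tone gains equalize perceived loudness across
#' frequency: +8 dB at 67.32 Hz down to −9 dB at 2154.33 Hz. A separate
#' 100 Hz reference tone opens each cycle at constant volume, anchoring
#' the listener's loudness scale.
#'
#' @param sample_rate Output sample rate in Hz (default 44100; the
#'   device can also run at 22050).
#' @param base_amplitude Peak amplitude of a 0 dB tone (default 0.2).
#' @param reference_freq Reference-tone frequency in Hz (default 100).
#' @param reference_gain_db Reference-tone gain in dB (default −6).
#' @param tones Optional replacement tone table (data.frame with columns
#'   `label`, `freq_hz`, `gain_db`, `scan`, `row`).
#' @return An object of class `"tone_bank"`.
#' @export
default_tone_bank <- function(sample_rate = 44100, base_amplitude = 0.2,
                              reference_freq = 100, reference_gain_db = -6,
                              tones = NULL) {
  if (is.null(tones)) {
    tones <- data.frame(
      label   = c("C7+", "G5+", "Ais4+", "G4+", "E3+", "C2+"),
      freq_hz = c(2154.33, 806.97, 479.86, 403.49, 169.63, 67.32),
      gain_db = c(-9, -2, -4, -4, 5, 8),
      scan    = c("upper", "upper", "upper", "lower", "lower", "lower"),
      row     = 0:5,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("label", "freq_hz", "gain_db", "scan", "row") %in%
                  names(tones)))
  if (any(tones$freq_hz <= 0)) stop("tone frequencies must be > 0",
                                    call. = FALSE)
  for (sc in unique(tones$scan)) {
    f <- tones$freq_hz[tones$scan == sc]
    if (anyDuplicated(f)) {
      stop("tones within one scan must have distinct frequencies",
           call. = FALSE)
    }
  }
  # higher grid row index = lower position in the image = lower tone
  ord <- order(tones$row)
  if (is.unsorted(rev(tones$freq_hz[ord]), strictly = TRUE)) {
    stop("tone frequency must strictly decrease from top row to bottom row",
         call. = FALSE)
  }
  structure(list(tones = tones, reference_freq = reference_freq,
                 reference_gain_db = reference_gain_db,
                 base_amplitude = base_amplitude, sample_rate = sample_rate),
            class = "tone_bank")
}

#' @export
print.tone_bank <- function(x, ...) {
  cat("<tone_bank> reference", x$reference_freq, "Hz, base amplitude",
      x$base_amplitude, ", rate", x$sample_rate, "Hz\n")
  print(x$tones, row.names = FALSE)
  invisible(x)
}

#' Build the cycle's phase schedule
#'
#' One transmission cycle is: a 300 ms reference tone, a 200 ms pause,
#' the upper scan (five 200 ms column slots, left to right), a pause, the
#' lower scan (five column slots, right to left), and a closing pause —
#' 14 events and 2900 ms at the defaults. Shorter timings support the
#' training progression of gradually compressed phases.
#'
#' @param reference_ms,pause_ms,column_ms Phase durations in ms
#'   (defaults 300, 200, 200).
#' @param cols Number of grid columns (default 5).
#' @return An object of class `"sonification_schedule"`: a data.frame of
#'   events with columns `kind` (`reference`/`pause`/`scan_column`),
#'   `duration_ms`, `scan` and `col` (0-based, NA for non-column events).
#' @export
build_schedule <- function(reference_ms = 300, pause_ms = 200,
                           column_ms = 200, cols = 5L) {
  if (any(c(reference_ms, pause_ms, column_ms) <= 0)) {
    stop("all phase durations must be > 0", call. = FALSE)
  }
  cols <- as.integer(cols)
  ev <- function(kind, dur, scan = NA_character_, col = NA_integer_) {
    data.frame(kind = kind, duration_ms = dur, scan = scan, col = col,
               stringsAsFactors = FALSE)
  }
  events <- rbind(
    ev("reference", reference_ms),
    ev("pause", pause_ms),
    do.call(rbind, lapply(0:(cols - 1L),
                          function(c) ev("scan_column", column_ms, "upper", c))),
    ev("pause", pause_ms),
    do.call(rbind, lapply((cols - 1L):0,
                          function(c) ev("scan_column", column_ms, "lower", c))),
    ev("pause", pause_ms)
  )
  rownames(events) <- NULL
  structure(events, class = c("sonification_schedule", "data.frame"),
            column_ms = column_ms)
}

#' Total duration of a schedule in milliseconds
#' @param schedule A [build_schedule()] result.
#' @return Total duration in ms.
#' @export
schedule_duration_ms <- function(schedule) sum(schedule$duration_ms)

#' Full-map transmission frequency of a schedule
#'
#' The reciprocal of the total cycle time: how often the whole depth map
#' is refreshed for the listener (0.345 Hz at the default 2900 ms cycle).
#'
#' @param schedule A [build_schedule()] result.
#' @return Frequency in Hz, rounded to 3 decimals.
#' @export
transmission_frequency <- function(schedule) {
  total <- schedule_duration_ms(schedule)
  if (total <= 0) stop("schedule has non-positive duration", call. = FALSE)
  round(1000 / total, 3)
}

#' Per-column (partial) refresh rate of a schedule
#'
#' Grid values are refreshed before each column slot, so within a scan
#' the listener receives a new column every `column_ms` (5 Hz at the
#' default 200 ms slots), ignoring inter-scan gaps.
#'
#' @param schedule A [build_schedule()] result.
#' @return Frequency in Hz.
#' @export
column_refresh_rate <- function(schedule) {
  1000 / attr(schedule, "column_ms")
}
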