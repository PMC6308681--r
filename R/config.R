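# Run configuration: one JSON file collecting the transform, grid,
# schedule, tone, audio and sensor settings; defaults reproduce the
# device's settings.

#' Assemble a full run configuration
#'
#' @param transform A [transform_spec()].
#' @param grid A [grid_config()].
#' @param schedule A [build_schedule()] result.
#' @param bank A [default_tone_bank()].
#' @param audio An [audio_config()].
#' @param sensor A [sensor_model()].
#' @param scn Optional [scene()].
#' @param seed Integer RNG seed (default 1).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(transform = transform_spec("linear"),
                       grid = grid_config(),
                       schedule = build_schedule(),
                       bank = default_tone_bank(),
                       audio = audio_config(),
                       sensor = sensor_model(),
                       scn = NULL, seed = 1L) {
  structure(list(transform = transform, grid = grid, schedule = schedule,
                 bank = bank, audio = audio, sensor = sensor, scn = scn,
                 seed = as.integer(seed)),
            class = "run_config")
}

.known_config_keys <- c("transform", "grid", "timings", "tones", "reference",
                        "audio", "sensor", "scene", "seed")

#' Read a run configuration from JSON
#'
#' Recognized top-level keys: `transform` (`{"id", "params"}`), `grid`
#' (`{"rows", "cols", "near_limit", "near_limit_raw", "method"}`),
#' `timings` (`{"reference_ms", "pause_ms", "column_ms"}`), `tones`
#' (list of `{"freq_hz", "gain_db", "scan", "row"}`), `reference`
#' (`{"freq_hz", "gain_db"}`), `audio` (`{"sample_rate", "hfov"}`),
#' `sensor`, `scene`, `seed`. Unknown keys are rejected; absent keys
#' take the device defaults.
#'
#' @param path Path to a JSON configuration file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  unknown <- setdiff(names(cfg), .known_config_keys)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sensor <- do.call(sensor_model, cfg$sensor %||% list())
  transform <- if (is.null(cfg$transform)) transform_spec("linear") else {
    transform_spec(cfg$transform$id, params = cfg$transform$params %||% list())
  }
  grid <- do.call(grid_config, c(cfg$grid %||% list(), list(sensor = sensor)))
  schedule <- do.call(build_schedule,
                      c(cfg$timings %||% list(), list(cols = grid$cols)))
  bank_args <- list()
  if (!is.null(cfg$tones)) {
    bank_args$tones <- do.call(rbind, lapply(cfg$tones, function(t) {
      data.frame(label = t$label %||% sprintf("%.2fHz", t$freq_hz),
                 freq_hz = t$freq_hz, gain_db = t$gain_db,
                 scan = t$scan, row = t$row, stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(cfg$reference)) {
    bank_args$reference_freq <- cfg$reference$freq_hz %||% 100
    bank_args$reference_gain_db <- cfg$reference$gain_db %||% -6
  }
  audio <- do.call(audio_config, cfg$audio %||% list())
  bank_args$sample_rate <- audio$sample_rate
  bank <- do.call(default_tone_bank, bank_args)
  scn <- if (is.null(cfg$scene)) NULL else {
    scene(objects = cfg$scene$objects %||% list(),
          dropout = cfg$scene$dropout %||% 0,
          seed = cfg$scene$seed %||% (cfg$seed %||% 1L))
  }
  run_config(transform = transform, grid = grid, schedule = schedule,
             bank = bank, audio = audio, sensor = sensor, scn = scn,
             seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
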