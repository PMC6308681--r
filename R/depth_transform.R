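# Distance-to-volume transfer functions.
#
# The sensor reports depth per pixel as an 11-bit raw reading in [0, 2047]:
# 488 is the nearest readable distance (~0.57 m) and 2047 is a reserved
# sentinel meaning "could not be read". The audio mixer takes an 8-bit
# volume code where 0 is loudest (nearest) and 255 is silence, so raw
# readings must be squeezed into [0, 255] by a monotone transfer function.

RAW_MAX <- 2047L
RAW_INVALID <- 2047L
RAW_MIN_VALID <- 488L
CODE_SILENCE <- 255L

.builtin_transform_params <- list(
  linear        = list(divisor = 2.215, offset = 488),
  gamma_adapted = list(scale = 36 * 256, offset = 1244.44, normalizer = 2048,
                       exponent = 3),
  own1          = list(base = 2, raw_divisor = 80, outer_divisor = 36,
                       offset = 1),
  own2          = list(scale = 36 * 256, offset = 3004.1, normalizer = 2048,
                       exponent = 3)
)

#' Create a distance-to-volume transfer specification
#'
#' Four built-in transfer functions map a raw 11-bit depth reading to a
#' real-valued volume level (later rounded and clamped into \[0, 255\]):
#'
#' * `linear`: `(raw - 488) / 2.215` — pure rescaling of the raw range,
#'   suited to tight indoor spaces.
#' * `gamma_adapted`: `(raw / 2048)^3 * 36 * 256 - 1244.44` — a cubic
#'   (gamma-style) curve rescaled into the 8-bit range.
#' * `own1`: `2^(raw / 80) / 36 - 1` — an empirical exponential curve,
#'   more suitable in the open air.
#' * `own2`: `(raw / 2048)^3 * 36 * 256 - 3004.1` — like `gamma_adapted`
#'   but shifted so the far end never reaches total silence and the very
#'   nearest distances saturate at maximum volume.
#'
#' All constants can be overridden through `params`; `id = "custom"` takes
#' an arbitrary vectorized function of the raw reading via `fn`.
#'
#' @param id One of `"linear"`, `"gamma_adapted"`, `"own1"`, `"own2"`,
#'   `"custom"`.
#' @param params Named list of constant overrides for a built-in id.
#' @param fn For `id = "custom"`, a vectorized function raw -> real level.
#' @return An object of class `"transform_spec"`.
#' @examples
#' spec <- transform_spec("linear")
#' eval_transform(spec, c(488, 1053, 2047))
#' @export
transform_spec <- function(id = c("linear", "gamma_adapted", "own1", "own2",
                                  "custom"),
                           params = list(), fn = NULL) {
  id <- match.arg(id)
  if (id == "custom") {
    if (!is.function(fn)) {
      stop("a custom transform_spec requires a function `fn`", call. = FALSE)
    }
    spec <- structure(list(id = id, params = params, fn = fn),
                      class = "transform_spec")
    return(spec)
  }
  defaults <- .builtin_transform_params[[id]]
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stop("unknown params for transform '", id, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  p <- modifyList(defaults, params)
  vals <- unlist(p)
  if (!all(is.finite(vals))) stop("transform params must be finite", call. = FALSE)
  pos <- intersect(names(p), c("divisor", "normalizer", "raw_divisor",
                               "outer_divisor"))
  if (any(unlist(p[pos]) <= 0)) {
    stop("divisors and normalizers must be strictly positive", call. = FALSE)
  }
  structure(list(id = id, params = p, fn = NULL), class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  cat("<transform_spec>", x$id, "\n")
  if (x$id != "custom") {
    cat(" ", paste(names(x$params), unlist(x$params), sep = " = ",
                   collapse = ", "), "\n")
  }
  invisible(x)
}

# Real-valued transfer level, before rounding/clamping. Vectorized.
transform_level <- function(spec, raw) {
  p <- spec$params
  switch(spec$id,
    linear        = (raw - p$offset) / p$divisor,
    gamma_adapted = (raw / p$normalizer)^p$exponent * p$scale - p$offset,
    own1          = p$base^(raw / p$raw_divisor) / p$outer_divisor - p$offset,
    own2          = (raw / p$normalizer)^p$exponent * p$scale - p$offset,
    custom        = spec$fn(raw)
  )
}

.check_raw <- function(raw) {
  if (!is.numeric(raw) || any(!is.finite(raw)) || any(raw != trunc(raw)) ||
      any(raw < 0) || any(raw > RAW_MAX)) {
    stop("raw readings must be integers in [0, 2047]", call. = FALSE)
  }
}

#' Evaluate a transfer function on raw depth readings
#'
#' The formula is evaluated in real arithmetic, rounded to the nearest
#' integer (ties away from zero) and clamped into \[0, 255\]. The sentinel
#' reading 2047 (unreadable point) always maps to 255 (silence),
#' regardless of the transfer function.
#'
#' @param spec A [transform_spec()].
#' @param raw Integer vector of raw readings in \[0, 2047\].
#' @return Integer vector of volume codes in \[0, 255\].
#' @export
eval_transform <- function(spec, raw) {
  stopifnot(inherits(spec, "transform_spec"))
  .check_raw(raw)
  code <- as.integer(pmin(255, pmax(0, round_half_away(transform_level(spec, raw)))))
  code[raw == RAW_INVALID] <- CODE_SILENCE
  code
}

#' Precompute the 2048-entry raw-to-volume lookup table
#'
#' Tabulates [eval_transform()] over every possible 11-bit raw reading so
#' that per-pixel conversion is a single index. The table also keeps the
#' clamped real-valued levels, used when small-field aggregation averages
#' codes without double rounding.
#'
#' @param spec A [transform_spec()].
#' @return An object of class `"volume_lut"` with fields `entries`
#'   (2048 integer codes, index = raw + 1), `levels` (clamped reals) and
#'   `spec`.
#' @export
build_lookup_table <- function(spec) {
  stopifnot(inherits(spec, "transform_spec"))
  raw <- 0:RAW_MAX
  levels <- pmin(255, pmax(0, transform_level(spec, raw)))
  levels[RAW_MAX + 1L] <- 255
  structure(list(entries = eval_transform(spec, raw),
                 levels = as.numeric(levels),
                 spec = spec),
            class = "volume_lut")
}

#' @export
print.volume_lut <- function(x, ...) {
  cat("<volume_lut>", x$spec$id, "- 2048 entries\n")
  nz <- which(x$entries > 0)[1] - 1L
  sat <- which(x$entries == 255)[1] - 1L
  cat("  first non-zero code at raw", nz,
      "| first silence code at raw", sat, "\n")
  invisible(x)
}

# Volume code(s) for raw reading(s) via a lookup table.
lut_code <- function(lut, raw) lut$entries[raw + 1L]
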