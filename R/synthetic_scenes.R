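# Synthetic depth scenes: a pinhole sensor model with the structured-
# light camera's field of view, raw<->metric calibration and dropout
# noise, standing in for the physical device.

#' Kinect-v1-like sensor model
#'
#' Field of view 57 x 43 degrees, 640 x 480 depth resolution, valid
#' metric range ~0.57–9 m, invalid-reading sentinel 2047. The raw-to-
#' metric characteristic uses the classical tangent disparity
#' approximation `z = a * tan(raw / b + c)`; the default constants
#' (0.1236, 2842.5, 1.1863) reproduce the device's printed calibration
#' point — raw 488 at the ~57 cm near limit — within 5 mm.
#'
#' @param hfov,vfov Field of view in degrees (defaults 57 and 43).
#' @param width,height Depth-map resolution (defaults 640 x 480).
#' @param min_range,max_range Valid metric range in metres (defaults
#'   0.57 and 9).
#' @param a,b,c Calibration constants of the tangent model.
#' @return An object of class `"sensor_model"`.
#' @export
sensor_model <- function(hfov = 57, vfov = 43, width = 640L, height = 480L,
                         min_range = 0.57, max_range = 9,
                         a = 0.1236, b = 2842.5, c = 1.1863) {
  structure(list(hfov = hfov, vfov = vfov,
                 width = as.integer(width), height = as.integer(height),
                 min_range = min_range, max_range = max_range,
                 invalid = RAW_INVALID, a = a, b = b, c = c),
            class = "sensor_model")
}

#' Convert raw sensor readings to metric depth
#'
#' `z = a * tan(raw / b + c)`, monotone increasing over the sensor's
#' useful raw band (raw 488 maps to ~0.574 m, raw ~1054 to 9 m).
#'
#' @param raw Raw reading(s).
#' @param sensor A [sensor_model()].
#' @return Depth in metres.
#' @export
raw_to_metric <- function(raw, sensor = sensor_model()) {
  sensor$a * tan(raw / sensor$b + sensor$c)
}

#' Convert metric depth to the nearest raw sensor reading
#'
#' Closed-form inverse of [raw_to_metric()], rounded to the nearest
#' integer. Depths outside the sensor's valid range (or non-finite) map
#' to the invalid code 2047.
#'
#' @param z Depth(s) in metres.
#' @param sensor A [sensor_model()].
#' @return Integer raw reading(s).
#' @export
metric_to_raw <- function(z, sensor = sensor_model()) {
  raw <- as.integer(round_half_away((atan(z / sensor$a) - sensor$c) * sensor$b))
  bad <- !is.finite(z) | z < sensor$min_range | z > sensor$max_range
  raw[bad] <- sensor$invalid
  raw
}

#' Describe a synthetic 3-D scene
#'
#' Scenes are lists of simple solids in the sensor's camera coordinates
#' (x right, y up, z forward along the optical axis, metres):
#'
#' * `list(type = "box", center = c(x, y, z), size = c(sx, sy, sz))` —
#'   an axis-aligned box;
#' * `list(type = "plane", z = z0)` — a fronto-parallel plane filling the
#'   field of view (optionally bounded via `center`/`size` in x/y);
#' * `list(type = "plane", point = c(x, y, z), normal = c(nx, ny, nz))` —
#'   an unbounded oblique plane.
#'
#' @param objects List of object descriptions as above.
#' @param dropout Probability that a pixel is replaced by the invalid
#'   code, emulating unreadable points (default 0).
#' @param seed RNG seed for the dropout draw (default 1).
#' @return An object of class `"scene"`.
#' @export
scene <- function(objects = list(), dropout = 0, seed = 1L) {
  if (dropout < 0 || dropout > 1) stop("dropout must be in [0, 1]",
                                       call. = FALSE)
  for (obj in objects) {
    if (is.null(obj$type) || !obj$type %in% c("box", "plane")) {
      stop("objects must have type 'box' or 'plane'", call. = FALSE)
    }
    if (obj$type == "box" && any(obj$size <= 0)) {
      stop("box sizes must be positive", call. = FALSE)
    }
  }
  structure(list(objects = objects, dropout = dropout,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "scene")
}

#' Read a scene description from JSON
#'
#' Expected shape:
#' `{"objects":[{"type":"box","center":[x,y,z],"size":[sx,sy,sz]},...],
#' "dropout":p,"seed":s}`.
#'
#' @param path Path to a JSON file.
#' @return A [scene()].
#' @export
read_scene_json <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  unknown <- setdiff(names(cfg), c("objects", "dropout", "seed"))
  if (length(unknown)) {
    stop("unknown scene keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  objects <- lapply(cfg$objects, function(o) {
    o[c("center", "size", "point", "normal")] <-
      lapply(o[c("center", "size", "point", "normal")],
             function(v) if (is.null(v)) NULL else as.numeric(v))
    o[!vapply(o, is.null, logical(1))]
  })
  scene(objects = objects,
        dropout = if (is.null(cfg$dropout)) 0 else cfg$dropout,
        seed = if (is.null(cfg$seed)) 1L else cfg$seed)
}

# Per-pixel ray direction tangents. Pixel centres are uniform in the
# tangent plane; row 1 is the top of the image (positive elevation).
.pixel_tangents <- function(sensor) {
  tx <- tan(sensor$hfov / 2 * pi / 180) *
    (2 * (seq_len(sensor$width) - 0.5) / sensor$width - 1)
  ty <- tan(sensor$vfov / 2 * pi / 180) *
    (1 - 2 * (seq_len(sensor$height) - 0.5) / sensor$height)
  list(tx = tx, ty = ty)
}

# z-interval [lo, hi] in which a ray (tx, ty, 1)*z stays inside [c0, c1]
# along one lateral axis. Returns matrices conformable with TX.
.slab_interval <- function(tangent, c0, c1) {
  lo <- ifelse(tangent > 0, c0 / tangent,
               ifelse(tangent < 0, c1 / tangent,
                      ifelse(c0 <= 0 & c1 >= 0, -Inf, Inf)))
  hi <- ifelse(tangent > 0, c1 / tangent,
               ifelse(tangent < 0, c0 / tangent,
                      ifelse(c0 <= 0 & c1 >= 0, Inf, -Inf)))
  list(lo = lo, hi = hi)
}

#' Cast rays through a scene to a metric depth map
#'
#' Pinhole camera at the origin looking down +z. Depth follows the
#' sensor's convention: the z-coordinate of the nearest intersection
#' (distance from the plane perpendicular to the optical axis), not the
#' length of the ray. Pixels that hit nothing are `Inf`.
#'
#' @param scn A [scene()].
#' @param sensor A [sensor_model()].
#' @return Numeric height x width matrix of depths in metres.
#' @export
ray_cast <- function(scn, sensor = sensor_model()) {
  stopifnot(inherits(scn, "scene"))
  tg <- .pixel_tangents(sensor)
  TX <- matrix(tg$tx, sensor$height, sensor$width, byrow = TRUE)
  TY <- matrix(tg$ty, sensor$height, sensor$width)
  depth <- matrix(Inf, sensor$height, sensor$width)
  for (obj in scn$objects) {
    if (obj$type == "box") {
      x0 <- obj$center[1] - obj$size[1] / 2; x1 <- obj$center[1] + obj$size[1] / 2
      y0 <- obj$center[2] - obj$size[2] / 2; y1 <- obj$center[2] + obj$size[2] / 2
      z0 <- obj$center[3] - obj$size[3] / 2; z1 <- obj$center[3] + obj$size[3] / 2
      if (z0 <= 0) stop("objects must lie entirely in front of the camera",
                        call. = FALSE)
      ix <- .slab_interval(TX, x0, x1)
      iy <- .slab_interval(TY, y0, y1)
      zen <- pmax(ix$lo, iy$lo, z0)
      zex <- pmin(ix$hi, iy$hi, z1)
      hit <- zen <= zex
      depth[hit] <- pmin(depth[hit], zen[hit])
    } else if (!is.null(obj$normal)) {
      # oblique plane: n . (d * (tx, ty, 1)) = n . p
      n <- obj$normal; p <- obj$point
      denom <- n[1] * TX + n[2] * TY + n[3]
      d <- sum(n * p) / denom
      hit <- is.finite(d) & d > 0
      depth[hit] <- pmin(depth[hit], d[hit])
    } else {
      z0 <- obj$z
      if (z0 <= 0) stop("plane must lie in front of the camera", call. = FALSE)
      hit <- matrix(TRUE, sensor$height, sensor$width)
      if (!is.null(obj$center) && !is.null(obj$size)) {
        hit <- abs(z0 * TX - obj$center[1]) <= obj$size[1] / 2 &
               abs(z0 * TY - obj$center[2]) <= obj$size[2] / 2
      }
      depth[hit] <- pmin(depth[hit], z0)
    }
  }
  depth
}

#' Generate a raw depth frame from a synthetic scene
#'
#' Ray-casts the scene, converts metric depths to raw readings (out-of-
#' range depths and misses become the invalid code 2047) and applies
#' i.i.d. per-pixel dropout with the scene's seeded RNG, so a fixed seed
#' yields an identical frame on every run.
#'
#' @param scn A [scene()].
#' @param sensor A [sensor_model()].
#' @return A [raw_depth_frame()].
#' @export
generate_frame <- function(scn, sensor = sensor_model()) {
  depth <- ray_cast(scn, sensor)
  raw <- matrix(metric_to_raw(depth, sensor), sensor$height, sensor$width)
  if (scn$dropout > 0) {
    if (!is.null(scn$seed)) set.seed(scn$seed)
    drop <- matrix(runif(length(raw)) < scn$dropout,
                   sensor$height, sensor$width)
    raw[drop] <- sensor$invalid
  }
  raw_depth_frame(raw)
}
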