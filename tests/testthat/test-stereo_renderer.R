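bank <- default_tone_bank()
lut_linear <- build_lookup_table(transform_spec("linear"))

grid_with <- function(codes = 255L, set = NULL) {
  m <- matrix(as.integer(codes), 6, 5)
  if (!is.null(set)) m[set$row + 1L, set$col + 1L] <- set$code
  structure(list(codes = m, valid_counts = matrix(1L, 6, 5),
                 config = grid_config()),
            class = "small_field_grid")
}

test_that("volume codes map linearly to amplitude factors", {
  expect_equal(volume_gain(255), 0)
  expect_equal(volume_gain(0), 1)
  expect_equal(volume_gain(127), 128 / 255)
  expect_error(volume_gain(256), "\\[0, 255\\]")
  expect_error(volume_gain(-1), "\\[0, 255\\]")
})

test_that("columns pan to the centres of their angular sectors", {
  expect_equal(column_azimuth(2, 5, 57), 0)
  expect_equal(column_azimuth(0, 5, 57), -22.8)
  expect_equal(column_azimuth(4, 5, 57), 22.8)
  expect_error(column_azimuth(5, 5, 57), "col")
})

test_that("pan gains conserve power across the whole arc", {
  for (az in seq(-90, 90, by = 1.5)) {
    g <- pan_gains(az)
    expect_equal(g[["left"]]^2 + g[["right"]]^2, 1, tolerance = 1e-9)
  }
  expect_equal(pan_gains(0), c(left = sqrt(0.5), right = sqrt(0.5)))
  expect_equal(pan_gains(-90), c(left = 1, right = 0))
  expect_equal(pan_gains(90), c(left = 0, right = 1), tolerance = 1e-15)
  # right gain grows monotonically as the image moves right
  rights <- vapply(seq(-90, 90, by = 5),
                   function(a) pan_gains(a)[["right"]], numeric(1))
  expect_true(all(diff(rights) > 0))
})

test_that("tone synthesis has the requested length and gained amplitude", {
  audio <- audio_config()
  tone <- synthesize_tone(100, 300, 0, bank, audio)
  expect_length(tone, 13230)  # 0.3 s * 44100
  # +8 dB on a 0.2 base: peak 0.2 * 10^0.4 = 0.5024
  loud <- synthesize_tone(67.32, 300, 8, bank, audio)
  expect_equal(max(abs(loud)), 0.2 * 10^0.4, tolerance = 1e-3)
  expect_true(all(synthesize_tone(440, 50, -Inf, bank, audio) == 0))
  expect_warning(over <- synthesize_tone(440, 50, 20, bank, audio),
                 "full scale")
  expect_lte(max(abs(over)), 1)
})

test_that("a rendered cycle has one sample per scheduled millisecond", {
  buf <- render_cycle(grid_with(255L), bank, build_schedule(), audio_config())
  expect_length(buf$left, 127890)  # 2.9 s * 44100
  expect_length(buf$right, 127890)
  expect_equal(buf$sample_rate, 44100)
  # per-event sample counts concatenate exactly
  rate22 <- audio_config(sample_rate = 22050)
  bank22 <- default_tone_bank(sample_rate = 22050)
  buf22 <- render_cycle(grid_with(255L), bank22, build_schedule(), rate22)
  expect_length(buf22$left, sum(round(build_schedule()$duration_ms * 22.050)))
})

test_that("an all-silent grid renders only the reference tone", {
  buf <- render_cycle(grid_with(255L))
  n_ref <- round(300 * 44100 / 1000)
  expect_gt(sqrt(mean(buf$left[1:n_ref]^2)), 0.01)
  expect_true(all(buf$left[(n_ref + 1):length(buf$left)] == 0))
  expect_true(all(buf$right[(n_ref + 1):length(buf$right)] == 0))
})

test_that("a nearer cell is never quieter within its slot", {
  sched <- build_schedule()
  slot_rms <- function(code) {
    buf <- render_cycle(grid_with(255L, set = list(row = 0, col = 1,
                                                   code = code)),
                        bank, sched, audio_config())
    ns <- round(sched$duration_ms * 44.1)
    ends <- cumsum(ns)
    i <- which(sched$kind == "scan_column" & sched$col == 1 &
               sched$scan == "upper")
    sqrt(mean(buf$left[(ends[i] - ns[i] + 1):ends[i]]^2 +
              buf$right[(ends[i] - ns[i] + 1):ends[i]]^2))
  }
  rms <- vapply(c(250, 200, 120, 60, 0), slot_rms, numeric(1))
  expect_true(all(diff(rms) > 0))
})

test_that("a single near cell at top-right sounds in the right slot, tone and ear", {
  sched <- build_schedule()
  buf <- render_cycle(grid_with(255L, set = list(row = 0, col = 4, code = 0)),
                      bank, sched, audio_config())
  loc <- localize_cycle(buf, sched, bank)
  expect_identical(loc$row, 0L)
  expect_identical(loc$col, 4L)
  # right channel carries more energy than the left for a rightmost column
  ns <- round(sched$duration_ms * 44.1)
  ends <- cumsum(ns)
  i <- which(sched$kind == "scan_column" & sched$col == 4 &
             sched$scan == "upper")
  seg <- (ends[i] - ns[i] + 1):ends[i]
  expect_gt(sqrt(mean(buf$right[seg]^2)), sqrt(mean(buf$left[seg]^2)))
})

test_that("grids whose shape disagrees with the bank or schedule are rejected", {
  small <- structure(list(codes = matrix(255L, 3, 5),
                          valid_counts = matrix(1L, 3, 5),
                          config = grid_config(rows = 3, cols = 5)),
                     class = "small_field_grid")
  expect_error(render_cycle(small), "tone bank")
  narrow <- structure(list(codes = matrix(255L, 6, 3),
                           valid_counts = matrix(1L, 6, 3),
                           config = grid_config(rows = 6, cols = 3)),
                      class = "small_field_grid")
  expect_error(render_cycle(narrow), "beyond the grid")
})

test_that("WAV files round-trip within one quantization step", {
  buf <- render_cycle(grid_with(128L))
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(buf, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 44100)
  expect_length(back$left, length(buf$left))
  expect_lt(max(abs(back$left - buf$left)), 1 / 32768)
  expect_lt(max(abs(back$right - buf$right)), 1 / 32768)
  # header-derived duration
  expect_equal(length(back$left) / back$sample_rate, 2.9)
})
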