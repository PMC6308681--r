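lut_linear <- build_lookup_table(transform_spec("linear"))

test_that("the default grid tiles a 640x480 frame into 30 blocks of 128x80", {
  frame <- uniform_frame(1000)
  blocks <- partition(frame, grid_config())
  expect_identical(dim(blocks), c(6L, 5L))
  expect_true(all(vapply(blocks, function(b) identical(dim(b), c(80L, 128L)),
                         logical(1))))
  # exact tiling: pixel count and value mass are conserved
  expect_identical(sum(vapply(blocks, length, integer(1))), 307200L)
  frame2 <- raw_depth_frame(matrix(sample(0:2047, 307200, replace = TRUE),
                                   480, 640))
  blocks2 <- partition(frame2, grid_config())
  expect_identical(sum(vapply(blocks2, function(b) sum(as.numeric(b)),
                              numeric(1))),
                   sum(as.numeric(frame2$values)))
})

test_that("a 1x1 grid is the identity partition", {
  frame <- uniform_frame(900, width = 20, height = 12)
  blocks <- partition(frame, grid_config(rows = 1, cols = 1))
  expect_identical(blocks[[1, 1]], frame$values)
})

test_that("non-divisible frame dimensions are a configuration error", {
  frame <- uniform_frame(900, width = 641, height = 480)
  expect_error(partition(frame, grid_config()), "not divisible")
})

test_that("field aggregation follows the four-step algorithm", {
  cfg <- grid_config()
  # near obstacle: min raw 488 <= 801 triggers the minimum override
  expect_identical(aggregate_field(matrix(488L, 4, 4), lut_linear, cfg), 0L)
  # far uniform field: mean of identical codes (1000-488)/2.215 = 231.2
  expect_identical(aggregate_field(matrix(1000L, 4, 4), lut_linear, cfg), 231L)
  # all-invalid field is silence
  expect_identical(aggregate_field(matrix(2047L, 4, 4), lut_linear, cfg), 255L)
  # mixed far field: mean of real codes 186.00 and 231.15 -> 208.58 -> 209
  block <- matrix(c(rep(900L, 8), rep(1000L, 8)), 4, 4)
  expect_identical(aggregate_field(block, lut_linear, cfg), 209L)
  # invalid pixels are excluded from the average
  block2 <- matrix(c(rep(1000L, 8), rep(2047L, 8)), 4, 4)
  expect_identical(aggregate_field(block2, lut_linear, cfg), 231L)
})

test_that("min-only aggregation takes the code of the nearest reading", {
  cfg <- grid_config(method = "min_only")
  block <- matrix(c(rep(900L, 8), rep(1000L, 8)), 4, 4)
  expect_identical(aggregate_field(block, lut_linear, cfg),
                   lut_linear$entries[901])
  expect_identical(aggregate_field(matrix(2047L, 2, 2), lut_linear, cfg), 255L)
})

test_that("a tie at the near limit counts as a near obstacle", {
  cfg <- grid_config()
  block <- matrix(c(cfg$near_limit_raw, rep(1500L, 15)), 4, 4)
  expect_identical(aggregate_field(block, lut_linear, cfg),
                   lut_linear$entries[cfg$near_limit_raw + 1L])
})

test_that("mapping a uniform frame gives 30 equal fields", {
  grid <- map_frame(uniform_frame(1000), lut_linear)
  expect_identical(dim(grid$codes), c(6L, 5L))
  expect_true(all(grid$codes == 231L))
  expect_true(all(grid$valid_counts == 128L * 80L))
})

test_that("a single near block lights up exactly one field", {
  vals <- matrix(1500L, 480, 640)
  vals[81:160, 129:256] <- 500L  # grid cell row 2, col 2 (1-based)
  grid <- map_frame(raw_depth_frame(vals), lut_linear)
  expect_identical(grid$codes[2, 2], lut_linear$entries[501])  # code 5
  expect_true(all(grid$codes[-(2 + 6 * 1)] == 255L))  # (1500-488)/2.215 clamps
})

test_that("an all-invalid frame maps to full silence with zero valid counts", {
  grid <- map_frame(uniform_frame(2047), lut_linear)
  expect_true(all(grid$codes == 255L))
  expect_true(all(grid$valid_counts == 0L))
})

test_that("min-only codes never exceed averaged codes; counts are conserved", {
  set.seed(21)
  for (rep in 1:25) {
    vals <- matrix(random_raws(10 * 12), 12, 10)
    frame <- raw_depth_frame(vals)
    cfg_avg <- grid_config(rows = 2, cols = 2)
    cfg_min <- grid_config(rows = 2, cols = 2, method = "min_only")
    g_avg <- map_frame(frame, lut_linear, cfg_avg)
    g_min <- map_frame(frame, lut_linear, cfg_min)
    expect_true(all(g_min$codes <= g_avg$codes))
    expect_identical(sum(g_avg$valid_counts), sum(vals != 2047L))
  }
})

test_that("aggregation agrees with the brute-force oracle on random frames", {
  set.seed(37)
  for (id in c("linear", "own2")) {
    spec <- transform_spec(id)
    lut <- build_lookup_table(spec)
    for (rep in 1:150) {
      vals <- matrix(random_raws(10 * 12), 12, 10)
      method <- sample(c("averaged", "min_only"), 1)
      cfg <- grid_config(rows = 2, cols = 2, method = method)
      grid <- map_frame(raw_depth_frame(vals), lut, cfg)
      for (r in 1:2) for (c in 1:2) {
        block <- vals[((r - 1) * 6 + 1):(r * 6), ((c - 1) * 5 + 1):(c * 5)]
        expect_identical(grid$codes[r, c],
                         oracle_aggregate(as.integer(block), id,
                                          cfg$near_limit_raw, method))
      }
    }
  }
})

test_that("grids round-trip through CSV", {
  grid <- map_frame(uniform_frame(950), lut_linear)
  path <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(grid, path)
  back <- read_grid_csv(path)
  expect_identical(back$codes, grid$codes)
  expect_true(all(is.na(back$valid_counts)))
})
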