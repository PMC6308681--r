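# Independent brute-force oracles, deliberately written without reusing
# any package internals: plain per-element loops and literal formulas.

oracle_round <- function(x) ifelse(x >= 0, floor(x + 0.5), ceiling(x - 0.5))

oracle_transform_level <- function(id, raw) {
  switch(id,
    linear        = (raw - 488) / 2.215,
    gamma_adapted = (raw / 2048)^3 * 36 * 256 - 1244.44,
    own1          = 2^(raw / 80) / 36 - 1,
    own2          = (raw / 2048)^3 * 36 * 256 - 3004.1
  )
}

oracle_transform <- function(id, raw) {
  out <- integer(length(raw))
  for (i in seq_along(raw)) {
    if (raw[i] == 2047) {
      out[i] <- 255L
    } else {
      v <- oracle_round(oracle_transform_level(id, raw[i]))
      out[i] <- as.integer(min(255, max(0, v)))
    }
  }
  out
}

# Four-step field aggregation, re-derived independently.
oracle_aggregate <- function(raws, id, near_limit_raw = 801,
                             method = "averaged") {
  valid <- raws[raws != 2047]
  if (length(valid) == 0) return(255L)
  m <- min(valid)
  if (method == "min_only") return(oracle_transform(id, m))
  if (m > near_limit_raw) {
    lv <- pmin(255, pmax(0, oracle_transform_level(id, valid)))
    as.integer(oracle_round(mean(lv)))
  } else {
    oracle_transform(id, m)
  }
}

# Raw readings with a realistic mixture: valid band, sentinels, extremes.
random_raws <- function(n) {
  pool <- c(sample(0:2046, n, replace = TRUE),
            sample(450:1100, 2 * n, replace = TRUE),
            rep(2047L, n))
  sample(pool, n)
}

uniform_frame <- function(raw, width = 640, height = 480) {
  raw_depth_frame(matrix(as.integer(raw), height, width))
}
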