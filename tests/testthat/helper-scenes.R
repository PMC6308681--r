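# Scene builders and a spectral localizer used by the end-to-end tests.

# Flat plate obstacle centred (in the tangent plane) on grid cell
# (row, col) at depth z, sized to stay strictly inside the cell; a
# fronto-parallel plate has no perspective spill into neighbours.
obstacle_scene_at <- function(row, col, z, sensor, jitter = c(0, 0)) {
  txc <- tan(sensor$hfov / 2 * pi / 180) * ((2 * col + 1) / 5 - 1)
  tyc <- tan(sensor$vfov / 2 * pi / 180) * (1 - (2 * row + 1) / 6)
  scene(list(list(type = "plane", z = z,
                  center = c(z * txc + jitter[1], z * tyc + jitter[2]),
                  size = c(0.15, 0.09))))
}

# From a rendered cycle, find the loudest column slot and the dominant
# tone in it; returns the implied grid cell.
localize_cycle <- function(buffer, schedule, bank) {
  rate <- buffer$sample_rate
  ns <- round(schedule$duration_ms * rate / 1000)
  ends <- cumsum(ns)
  starts <- ends - ns + 1
  idx <- which(schedule$kind == "scan_column")
  rms <- vapply(idx, function(i) {
    sqrt(mean(buffer$left[starts[i]:ends[i]]^2 +
              buffer$right[starts[i]:ends[i]]^2))
  }, numeric(1))
  best <- idx[which.max(rms)]
  seg <- buffer$left[starts[best]:ends[best]] +
         buffer$right[starts[best]:ends[best]]
  sp <- Mod(stats::fft(seg))[seq_len(length(seg) %/% 2)]
  freqs <- (seq_along(sp) - 1) * rate / length(seg)
  tones <- bank$tones[bank$tones$scan == schedule$scan[best], , drop = FALSE]
  energy <- vapply(tones$freq_hz,
                   function(f) max(sp[abs(freqs - f) < 15]), numeric(1))
  list(row = tones$row[which.max(energy)], col = schedule$col[best],
       slot_rms = rms)
}
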