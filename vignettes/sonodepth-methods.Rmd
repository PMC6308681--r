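---
title: "Depth-map sonification: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-map sonification: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonodepth)
```

## The problem

A structured-light depth camera worn on the head returns, at each pixel,
an 11-bit raw reading that grows monotonically with the distance to the
nearest surface — measured to the plane perpendicular to the optical
axis, not along the ray. The nearest readable distance (~0.57 m)
corresponds to raw 488; the code 2047 is reserved for points whose
distance could not be read (too close, too far, sunlight interference).
sonodepth turns such frames into a stream of stereo tones from which a
trained listener can reconstruct a coarse spatial map: *where* an
obstacle is (stereo position and pitch) and *how far* it is (loudness).

## Distance-to-volume transfer

The audio mixer takes an 8-bit volume code: 0 is maximum loudness, 255
is silence. A transfer function `d(raw)` compresses the useful raw band
into that range; `transform_spec()` ships four:

| id | formula | character |
|---|---|---|
| `linear` | `(raw − 488) / 2.215` | pure rescale; saturates at raw ≈ 1053 (tight rooms) |
| `gamma_adapted` | `(raw/2048)³·36·256 − 1244.44` | cubic curve adapted from the sensor library's gamma demo |
| `own1` | `2^(raw/80)/36 − 1` | empirical exponential, better in the open air |
| `own2` | `(raw/2048)³·36·256 − 3004.1` | cubic shifted so the far end never fully silences and the nearest band saturates loud |

Two of the printed constant sets (`gamma_adapted`, `own2`) have useful
ranges that do not line up with the linear map's 0.57–9 m band — e.g.
`own2` is negative (clamped to full loudness) until raw ≈ 1409. The
constants are nevertheless implemented exactly as printed and exposed in
`params`, because the device's usability explicitly depends on hand
tuning these curves; a `custom` id accepts any vectorized function. The
exponential transform's typeset form is ambiguous in its source; the
reading `2^(raw/80)/36 − 1` is adopted because it rises from ≈0 at raw
488 and reaches 255 at raw ≈ 1054 — the same saturation point as the
linear map and the ~9 m end of the sensor's range.

Numerical conventions (the source states none): formula values are
computed in real arithmetic, rounded to the nearest integer with ties
away from zero, then clamped to [0, 255]. Raw 2047 is short-circuited to
255 before any formula. Raw values below 488 — possible in synthetic
frames with noise — are evaluated and clamped rather than rejected.
`build_lookup_table()` tabulates all 2048 codes once; tests compare the
table exhaustively against direct evaluation and an independent oracle.

## The small-field grid

A full 640 × 480 frame carries far too much information for audio, and
unreadable patches would inject noise, so the frame is tiled into
6 rows × 5 columns of small fields (128 × 80 px each). Per field
(`aggregate_field()`):

1. every pixel is converted through the lookup table;
2. pixels with the sentinel 2047 are discarded; the valid codes are
   summed and counted, and the minimum raw reading is tracked;
3. if that minimum is farther than the near limit (default 1.2 m) and at
   least one pixel is valid, the field code is the rounded mean of the
   valid codes;
4. otherwise — a near obstacle — the field takes the minimum reading's
   code. No valid pixel at all yields 255 (silence).

Open points resolved here: the mean is taken over *transformed* codes
(the conversion step precedes the summation step), kept real-valued
until one final round to avoid double rounding; the near-limit
comparison runs in raw units (`min raw > near_limit_raw`, default 801,
derived once from 1.2 m through the sensor calibration and stored in the
config), which is equivalent to a metric comparison because every
transfer function is monotone; "too large" discarded values are exactly
the sentinel 2047, no other ceiling; a minimum exactly at the limit
counts as near. A `min_only` method (field = minimum reading's code) is
available as the simpler alternative; since transforms are monotone its
code can never exceed the averaged one, which tests assert.

## Tones and schedule

Six sine tones encode the six rows, higher row = higher pitch. They are
C-chord notes (C, E, G, A♯) spread over octaves and raised 50 cents —
the quarter-tone shift makes them unmistakable for common environmental
or musical pitches. `make_tone_frequency()` recomputes any of them in
equal temperament (A4 = 440 Hz, times `2^(cents/1200)`); the default
bank instead carries the device's printed values verbatim (2154.33,
806.97, 479.86, 403.49, 169.63, 67.32 Hz) because a few printed cells
differ from exact recomputation by up to 0.05 Hz (403.49 printed vs
403.48 recomputed) and the printed values are what the device played.
Per-tone gains (+8 dB at 67.32 Hz … −9 dB at 2154.33 Hz) equalize
perceived loudness across frequency. The upper scan (rows 0–2, top) gets
the three highest tones and the lower scan the three lowest — the
printed tone table encodes this assignment in colour, unreadable in
text, but the stated "three upper lines, three higher notes" fixes it;
it remains config-overridable.

The default cycle (`build_schedule()`): 300 ms reference tone (100 Hz,
fixed volume — a loudness anchor across quiet and noisy environments),
200 ms pause, five 200 ms column slots left→right carrying the upper
rows (three tones in parallel, each attenuated by its cell's code),
pause, five slots right→left for the lower rows, pause. Total 2900 ms:
0.345 Hz full-map refresh, 5 Hz per-column. All durations are free
parameters to support the training progression of gradually shortened
phases. The reference tone's loudness is not specified anywhere; the
default is −6 dB relative to the base amplitude, configurable.

## Stereo rendering

The mixer the original device delegated to is emulated explicitly:

* **Amplitude:** linear in the code, `(255 − code)/255`; the original
  mixer's distance-attenuation curve is unspecified.
* **Azimuth:** column `c` of `n` is placed at the centre of its angular
  sector of the 57° horizontal field of view:
  `−hfov/2 + (c + 0.5)·hfov/n`.
* **Pan law:** constant power, `left = cos θ`, `right = sin θ` with
  `θ = (azimuth + 90)/180 · π/2`, so `left² + right² = 1` everywhere.
* **Synthesis:** zero-phase sines at 44.1 kHz (22.05 kHz supported),
  base amplitude 0.2, per-slot 5 ms raised-cosine fades to avoid clicks;
  a slot whose mixed peak would clip is rescaled as a whole (warning),
  preserving relative levels. Output is 16-bit PCM stereo WAV.

## Learning mode

Pitch-for-height is not an innate mapping, so a training mode reduces
the task to one dimension: the minimum distance in the central small
field drives a single tone's loudness through the same lookup table as
normal mode, and the head tilt selects which row-tone plays — bins of
43°/6 ≈ 7.17° across the vertical field of view, silence beyond ±21.5°,
refreshed at 20 Hz (50 ms), with the reference pattern (200 ms pause,
300 ms reference, 200 ms pause) replacing every 80th reading, i.e.
every 4 s. Bin edges are half-open with the upper edge inclusive and the
lowest bin additionally closed at −21.5°, so the quantized tilt range is
tiled exactly; whether distance tones continue *during* the reference is
unstated, and replacement (not overlay) is chosen as the less confusing
behaviour for a trainee.

## Synthetic scenes

`sensor_model()` + `generate_frame()` replace the physical sensor:
axis-aligned boxes, bounded fronto-parallel plates and oblique planes
are ray-cast through a pinhole camera (pixel centres uniform in the
tangent plane), and the *z*-coordinate of the nearest hit — the
perpendicular-plane convention — is converted to a raw reading through
the tangent disparity model `z = 0.1236 · tan(raw/2842.5 + 1.1863)`.
The published device characteristic is only a plotted curve; this
classical approximation is adopted because it reproduces the one printed
calibration point (raw 488 at ~57 cm; the model gives 0.572 m) and is
monotone over the whole 0.57–9 m band. All constants are configurable.
Unreadable points are emulated as i.i.d. per-pixel dropout with a seeded
RNG, so frames are reproducible.

What the generator does *not* emulate: structured-light pattern physics,
sunlight interference (dropout is spatially uncorrelated, real dropouts
cluster), depth quantization noise beyond the raw integer grid, motion
blur, or an RGB channel. Passing tests therefore demonstrate the
*pipeline's* correctness — geometry, transfer, aggregation, schedule,
panning — not robustness to real sensor artefacts.

## Verification strategy and problem sizes

Most suites run at full 640 × 480 resolution. Two deliberately scaled
choices: the brute-force aggregation oracle runs 1000 random 10 × 12
frames with a 2 × 2 grid (every block checked against an independently
coded oracle), and the end-to-end localization suite renders 100 random
single-obstacle scenes at 160 × 120 (same field of view and grid; the
cell geometry is resolution-invariant) and 22.05 kHz, requiring that the
loudest column slot and the dominant tone of its spectrum identify the
obstacle's grid cell. Obstacles there are bounded fronto-parallel
plates centred inside a cell: a 3-D box's top/bottom face remains
visible slightly past the cell boundary under perspective and would
legitimately sound two adjacent rows, which is a property of boxes, not
a rendering error.

## Limitations

* Offline only: no live sensor acquisition, audio device output, or the
  device's plug-gesture mode switching.
* No head-related transfer functions or binaural rendering —
  lateralization is amplitude panning only, as in the original mixer.
* The transfer-function constants other than the linear map's are used
  as printed even where their useful ranges look inconsistent; choosing
  better constants is left to configuration.
* Human performance (navigation effectiveness with and without
  training) is outside what software can reproduce; this package only
  enables analogous simulations.
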