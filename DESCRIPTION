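Package: sonodepth
Title: Depth-Map Sonification for Assistive Spatial Orientation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts structured-light depth frames into a low-resolution
    acoustic image for non-visual spatial perception. Raw 11-bit depth
    readings are mapped to 8-bit volume codes through configurable
    distance-to-loudness transfer functions, downsampled to a 6-row by
    5-column small-field grid, and rendered as a timed stereo tone cycle
    (six quarter-tone-raised C7-chord tones, constant-power panning,
    16-bit PCM WAV output). Includes a tilt-driven learning mode that
    encodes head inclination as pitch, a parametric synthetic depth-scene
    generator emulating a Kinect-v1-like sensor (57 x 43 degree field of
    view, 640 x 480 resolution, invalid-code dropouts), and command-line
    entry points for offline rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
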