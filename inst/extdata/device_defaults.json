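{
  "transform": {"id": "own2"},
  "grid": {"rows": 6, "cols": 5, "near_limit": 1.2},
  "timings": {"reference_ms": 300, "pause_ms": 200, "column_ms": 200},
  "reference": {"freq_hz": 100, "gain_db": -6},
  "audio": {"sample_rate": 44100, "hfov": 57},
  "seed": 1
}
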