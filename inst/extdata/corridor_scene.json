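{
  "objects": [
    {"type": "plane", "z": 4.0},
    {"type": "box", "center": [-0.7, 0.0, 1.5], "size": [0.5, 1.8, 0.3]},
    {"type": "box", "center": [0.6, -0.5, 2.5], "size": [0.4, 0.4, 0.4]}
  ],
  "dropout": 0.02,
  "seed": 7
}
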