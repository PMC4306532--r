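{
  "occipital-L": {
    "center": [-15, -85, 5],
    "radius": 30
  },
  "occipital-R": {
    "center": [15, -85, 5],
    "radius": 30
  },
  "parietal-L": {
    "center": [-25, -60, 55],
    "radius": 30
  },
  "parietal-R": {
    "center": [25, -60, 55],
    "radius": 30
  },
  "frontal-L": {
    "center": [-35, -5, 50],
    "radius": 30
  },
  "frontal-R": {
    "center": [35, -5, 50],
    "radius": 30
  }
}
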