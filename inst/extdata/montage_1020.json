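{
  "positions": [
    {"name": "Fp1", "x": -0.4, "y": 0.95},
    {"name": "Fp2", "x": 0.4, "y": 0.95},
    {"name": "F7", "x": -0.9, "y": 0.55},
    {"name": "F3", "x": -0.5, "y": 0.5},
    {"name": "Fz", "x": 0.0, "y": 0.5},
    {"name": "F4", "x": 0.5, "y": 0.5},
    {"name": "F8", "x": 0.9, "y": 0.55},
    {"name": "T7", "x": -1.0, "y": 0.0},
    {"name": "C3", "x": -0.5, "y": 0.0},
    {"name": "Cz", "x": 0.0, "y": 0.0},
    {"name": "C4", "x": 0.5, "y": 0.0},
    {"name": "T8", "x": 1.0, "y": 0.0},
    {"name": "P7", "x": -0.9, "y": -0.55},
    {"name": "P3", "x": -0.5, "y": -0.5},
    {"name": "Pz", "x": 0.0, "y": -0.5},
    {"name": "P4", "x": 0.5, "y": -0.5},
    {"name": "P8", "x": 0.9, "y": -0.55},
    {"name": "O1", "x": -0.4, "y": -0.95},
    {"name": "O2", "x": 0.4, "y": -0.95}
  ],
  "neighbors": {
    "C3": ["F3", "Cz", "P3", "T7"],
    "C4": ["F4", "Cz", "P4", "T8"],
    "Cz": ["Fz", "C3", "C4", "Pz"]
  },
  "center": "C3"
}
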