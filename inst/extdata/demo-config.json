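{
  "seed": 1,
  "output_dir": "cuttleoptics-out",
  "stages": ["synth", "cardfit", "depthsim", "gamut", "survey", "scalebar"],
  "optics": {
    "k": [0.5, 0.07, 0.04],
    "surface_illuminant": [1.0, 1.0, 1.0],
    "noise_sd": 0.005
  },
  "depths": [0.0, 4.6, 6.0, 11.7, 11.8, 14.0, 17.2, 19.4, 21.1, 22.2, 25.7],
  "interpolation_mode": "exponential",
  "alternative": "deficit",
  "renormalize": false,
  "sim_depth": 10,
  "mm_per_px": 0.2,
  "dot_separation_mm": 100,
  "timezone_label": "local"
}
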