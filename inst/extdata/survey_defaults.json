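{
  "seed": 42,
  "outdir": "fluorquant_run",
  "stages": ["simulate", "process", "fit_peaks", "quantify"],
  "noise": { "sigma_per_scan": 1700 },
  "simulate": {
    "peaks": [ { "center": -120, "area": 34, "fwhm": 3 } ]
  },
  "process": { "lb": 2, "zero_fill": 2, "phi0": 0, "baseline": true },
  "fit_peaks": { "snr_threshold": 3, "window": 1.0, "noise_region": [-105, -95] },
  "quantify": {
    "standards": [1, 2.1544, 4.6416, 10, 21.5443, 46.4159, 100],
    "response": 1,
    "confidence": 0.95,
    "center": -120
  }
}
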