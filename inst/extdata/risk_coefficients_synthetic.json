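{
  "comment": "SYNTHETIC China-PAR-form composite ASCVD risk coefficients. Plausible magnitudes for a Chinese middle-aged/elderly population; NOT the published equation. risk = 1 - s0 ^ exp(LP - mean_lp). Units: age years, SBP mmHg, TC/HDL mmol/L, WC cm, smoker/diabetes 0-1.",
  "version": "synthetic-1.0",
  "male": {
    "coefficients": {
      "age": 0.074,
      "sbp_untreated": 0.017,
      "sbp_treated": 0.019,
      "tc": 0.065,
      "hdl": -0.70,
      "wc": 0.018,
      "smoker": 0.46,
      "diabetes": 0.52
    },
    "s0": 0.930,
    "mean_lp": 7.935
  },
  "female": {
    "coefficients": {
      "age": 0.079,
      "sbp_untreated": 0.018,
      "sbp_treated": 0.020,
      "tc": 0.029,
      "hdl": -0.42,
      "wc": 0.015,
      "smoker": 0.55,
      "diabetes": 0.66
    },
    "s0": 0.957,
    "mean_lp": 7.909
  }
}
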