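{
  "_comment": "SYNTHETIC PLACEHOLDER coefficient set for testing only. These are not the fitted values of the cited blood relaxometry / oxygen relaxivity publications; they were constructed from public literature anchors to reproduce the qualitative physics (signs, field dependence, magnitudes). Do not use for science-grade predictions.",
  "blood_coefficients": {
    "r1eox_b0": 0.87,
    "r1eox_b1": -0.08,
    "r1p_b0": 0.82,
    "r1p_b1": -0.053,
    "r1dhb_b0": 0.0,
    "r1dhb_b1": 0.075,
    "r1pox_b0": 0.00035,
    "r1pox_b1": -0.00003,
    "p50_blood": 37,
    "hill_n_blood": 2.7,
    "provenance": "placeholder"
  },
  "relaxivity_coefficients": {
    "c1": 0.00022,
    "c2": 0.21,
    "c3": 0.00024,
    "c_temp": -0.0000022,
    "provenance": "placeholder"
  }
}
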