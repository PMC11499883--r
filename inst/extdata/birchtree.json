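{
  "site": "Birchtree",
  "_comment": "Published Birchtree mine values. acetate_conc_M is a supplementary-sourced placeholder (0.1 mM), consistent with the published >0.1 nM/yr minimum turnover.",
  "temperature_C": 25,
  "water_d2H": -74,
  "acetate_d2H": [-167, -170],
  "acetate_d13C": [-26.7, -27.4],
  "acetate_conc_M": 1.0e-4,
  "threshold_permil": 50,
  "eie": {
    "anchors": [
      {"temperature_K": 298.15, "epsilon_permil": -192},
      {"temperature_K": 523.15, "epsilon_permil": -108}
    ],
    "salt_multiplier": 1.015
  }
}
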