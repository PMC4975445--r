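{
  "label": "wild_type_defaults",
  "params": {
    "k1": 5.7e-6,
    "k2": 1.5e9,
    "k2_sod": 2.8e4,
    "k1_prime": 12e-6,
    "vmax_ahp": 6.6e-4,
    "km_ahp": 1.2e-6,
    "vmax_cat": 4.9e-1,
    "km_cat": 5.9e-3,
    "kdiff": 70,
    "vin": 3.2e-15
  },
  "strains": [
    {"label": "wild_type", "ahp_factor": 1, "cat_factor": 1, "n0": "1.45e7 /mL"}
  ],
  "population": {"vout": "1 L", "growth_mode": "constant"},
  "stress_events": [{"time": "0 s", "amount": "1.5 uM"}],
  "t_end": "20 min"
}
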