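{
  "name": "weight_minus_10_percent",
  "perturbations": [
    {"variable": "weight_lbs", "kind": "multiplicative", "value": -0.10}
  ],
  "propagate": [
    {"from": "weight_lbs", "to": "bmi", "rule": "same_relative"}
  ]
}
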