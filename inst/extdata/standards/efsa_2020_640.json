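{
  "name": "efsa_2020_640",
  "description": "EU/EFSA limits for propolis: Cd 0.1 ppm, Pb 1 ppm, As must be absent; daily Mn intake bound 3 mg/day.",
  "limits": {
    "Cd": 0.1,
    "Pb": 1,
    "As": "absent"
  },
  "mn_intake_bound_mg_day": 3
}
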