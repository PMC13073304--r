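{
  "name": "iram_inta_15935",
  "description": "Argentine propolis standard: Pb 10 ppm, As 2 ppm.",
  "limits": {
    "Pb": 10,
    "As": 2
  }
}
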