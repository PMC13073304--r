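{
  "name": "nrag_1135",
  "description": "Cuban propolis standard NRAG-1135 (M32.1)-94: Pb 2 ppm, As 1 ppm.",
  "limits": {
    "Pb": 2,
    "As": 1
  }
}
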