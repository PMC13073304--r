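{
  "ingr": 0.001,
  "ef": 90,
  "ed": 40,
  "bw": 75,
  "at_rule": "match_ed",
  "life_expectancy": 75.5
}
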