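{
  "schema_version": "1.0",
  "required": [
    "schema_version",
    "qc",
    "censoring",
    "detection_frequency",
    "exceedance",
    "mn_intake",
    "correlation",
    "pca",
    "cluster",
    "risk"
  ]
}
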