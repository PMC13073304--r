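element,recovery_pct,rsd_pct,lod,loq
As,85.00,0.70,0.076,0.210
Cd,90.14,0.15,0.0028,0.008
Pb,94.90,2.60,0.010,0.045
Mn,97.27,0.05,0.076,0.210
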