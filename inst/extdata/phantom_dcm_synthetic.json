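{
  "label": "DCM phantom (synthetic wall law)",
  "c2": 0.0015,
  "c1": 0.3,
  "c0": 0,
  "V_0": 113,
  "C": 2.2222222222222223
}
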