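{
  "label": "HFpEF phantom (synthetic wall law)",
  "c2": 0.0035,
  "c1": 0.55,
  "c0": 0,
  "V_0": 32,
  "C": 1.1111111111111112
}
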