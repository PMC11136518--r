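{
  "label": "Healthy phantom (synthetic wall law)",
  "c2": 0.002,
  "c1": 0.4,
  "c0": 0,
  "V_0": 83,
  "C": 1.6666666666666667
}
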