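# Heart failure with preserved ejection fraction: stiff diastole, small
# cavity, preserved contractility. HR derived from CO = SV x HR.
label: HFpEF
hr_bpm: 67
co_l_min: 4.1
systemic_arterial_mmHg:
  systolic: 172
  diastolic: 69
  mean: 102
pulmonary_arterial_mmHg:
  systolic: 67
  diastolic: 25
  mean: 39
rap_mmHg: 15
pwedge_mmHg: 23
lv_ml:
  esv: 32
  edv: 93
rv_ml:
  esv: 52
  edv: 113
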