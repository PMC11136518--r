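# Healthy volunteer: normal contractility and diastolic function.
# Pwedge was not measured clinically ("/"); 10 mmHg is the bench
# personalization target. HR derived from CO = SV x HR.
label: Healthy
hr_bpm: 79
co_l_min: 4.9
systemic_arterial_mmHg:
  systolic: 152
  diastolic: 67
  mean: 94
pulmonary_arterial_mmHg:
  systolic: 32
  diastolic: 14
  mean: 20
rap_mmHg: 11
pwedge_mmHg: 10
lv_ml:
  esv: 83
  edv: 145
rv_ml:
  esv: 81
  edv: 143
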