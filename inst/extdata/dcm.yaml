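# Dilated cardiomyopathy: large cavity, poor contractility, impaired
# relaxation. HR derived from CO = SV x HR.
label: DCM
hr_bpm: 61
co_l_min: 4.3
systemic_arterial_mmHg:
  systolic: 145
  diastolic: 71
  mean: 96
pulmonary_arterial_mmHg:
  systolic: 26
  diastolic: 8
  mean: 17
rap_mmHg: 7
pwedge_mmHg: 10
lv_ml:
  esv: 113
  edv: 184
rv_ml:
  esv: 53
  edv: 124
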