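# Literature-default simulator parameters (provenance tag: literature).
# Units: pressures mmHg, volumes ml, time s, resistances mmHg s/ml,
# compliances ml/mmHg.
version: 1
dt: 0.001            # integration step, 1-ms real-time tick
rc_fraction: 0.05    # characteristic resistance as fraction of bed total
venous_fraction: 0.05  # fraction of R_p downstream of the venous node
venous_pressure_offset: 1.5  # initial venous pressure above atrial target
valves:
  mitral: 0.02      # AV-valve resistances bound peak early-filling flow
  aortic: 0.01      # to physiologic E-wave values (no inertance modeled)
  tricuspid: 0.02
  pulmonary: 0.01
venous_compliance:
  systemic: 60
  pulmonary: 15
atrium:              # weak active chambers, shared left/right defaults
  a: 0.4
  b: 0.04
  E_s: 0.35
  V_0: 10
  lead: 0.16         # atrial onset precedes ventricular onset (PR interval)
  duration: 0.10     # activation duration, fraction of cycle
ventricle:
  V_0: 5             # zero-pressure filling volume
  p_floor: 0.5       # diastolic anchor pressure at V_0
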