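profile,quantity,unit,clinical,echo,printed_error,determinable
HFpEF,lv_edv,ml,93,90,3.2,TRUE
HFpEF,lv_esv,ml,32,44,37.5,TRUE
Healthy,lv_edv,ml,145,146,0.7,TRUE
Healthy,lv_esv,ml,83,88,6,TRUE
DCM,lv_edv,ml,184,181,1.6,TRUE
DCM,lv_esv,ml,113,117,3.5,TRUE
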