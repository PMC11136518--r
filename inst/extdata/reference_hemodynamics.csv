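profile,quantity,unit,clinical,simulated,printed_error,determinable
HFpEF,CO,l/min,4.1,4.4,7.3,TRUE
HFpEF,sap_sys,mmHg,172,154,10.5,TRUE
HFpEF,sap_dia,mmHg,69,108,56.5,TRUE
HFpEF,sap_mean,mmHg,102,132,29.4,TRUE
HFpEF,pap_sys,mmHg,67,67,0,TRUE
HFpEF,pap_dia,mmHg,25,25,0,TRUE
HFpEF,pap_mean,mmHg,39,41,5.1,TRUE
HFpEF,Pwedge,mmHg,23,23,0,TRUE
HFpEF,RAP,mmHg,15,16,6.7,TRUE
HFpEF,lvp_sys,mmHg,,157,,TRUE
HFpEF,lvp_dia,mmHg,,11,,TRUE
HFpEF,rvp_sys,mmHg,67,66,1.5,TRUE
HFpEF,rvp_dia,mmHg,18,17,5.6,TRUE
HFpEF,lv_esv,ml,32,28,12.5,TRUE
HFpEF,lv_edv,ml,93,94,0.5,FALSE
HFpEF,rv_esv,ml,52,46,11.5,TRUE
HFpEF,rv_edv,ml,113,112,1.3,FALSE
Healthy,CO,l/min,4.9,4.8,2,TRUE
Healthy,sap_sys,mmHg,152,137,9.9,TRUE
Healthy,sap_dia,mmHg,67,87,29.9,TRUE
Healthy,sap_mean,mmHg,94,113,20.2,TRUE
Healthy,pap_sys,mmHg,32,33,3.1,TRUE
Healthy,pap_dia,mmHg,14,11,15.4,FALSE
Healthy,pap_mean,mmHg,20,20,0,TRUE
Healthy,Pwedge,mmHg,,10,,TRUE
Healthy,RAP,mmHg,11,11,0,TRUE
Healthy,lvp_sys,mmHg,,140,,TRUE
Healthy,lvp_dia,mmHg,,82,,TRUE
Healthy,rvp_sys,mmHg,32,34,8.1,FALSE
Healthy,rvp_dia,mmHg,13,12,7.7,TRUE
Healthy,lv_esv,ml,83,83,0,TRUE
Healthy,lv_edv,ml,145,144,0.9,FALSE
Healthy,rv_esv,ml,81,80,1.2,TRUE
Healthy,rv_edv,ml,143,141,1.6,FALSE
DCM,CO,l/min,4.3,4.5,4.7,TRUE
DCM,sap_sys,mmHg,145,126,13.1,TRUE
DCM,sap_dia,mmHg,71,82,15.5,TRUE
DCM,sap_mean,mmHg,96,104,8.3,TRUE
DCM,pap_sys,mmHg,26,29,11.5,TRUE
DCM,pap_dia,mmHg,8,11,37.5,TRUE
DCM,pap_mean,mmHg,17,18,5.9,TRUE
DCM,Pwedge,mmHg,10,11,10,TRUE
DCM,RAP,mmHg,7,8,14.3,TRUE
DCM,lvp_sys,mmHg,,130,,TRUE
DCM,lvp_dia,mmHg,,4,,TRUE
DCM,rvp_sys,mmHg,26,30,15.4,TRUE
DCM,rvp_dia,mmHg,10,8,20,TRUE
DCM,lv_esv,ml,113,115,1.8,TRUE
DCM,lv_edv,ml,184,189,2.9,FALSE
DCM,rv_esv,ml,53,50,5.7,TRUE
DCM,rv_edv,ml,124,124,0.2,FALSE
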