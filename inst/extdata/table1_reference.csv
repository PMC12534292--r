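subtype,n,male_n,duration_median,duration_q1,duration_q3,onset_age_median,tdp43_pos,tdp43_eval,early_om_present,early_om_eval
PSP-PF,188,119,6,5,7,66,5,157,122,147
PSP-RS,68,29,7,6,8,65,5,51,NA,NA
PSP-PI,204,98,8,7,10,67,12,162,NA,NA
PSP-P,36,25,10,8,10,68,1,26,NA,NA
PSP-SL,29,22,8,7,10,70,3,17,NA,NA
PSP-F,31,22,9,7,10,62,5,26,NA,NA
PSP-OM,13,7,8,7,10,65,0,10,NA,NA
Misc,19,12,9,7,10,65,0,15,NA,NA
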