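stat,object,label,source,value,digits
mean,mandible,Attempts,registration,1.45,2
sd,mandible,Attempts,registration,0.69,2
mean,mandible,FRE,registration,1.15,2
sd,mandible,FRE,registration,0.25,2
mean,graft,Attempts,registration,2.73,2
sd,graft,Attempts,registration,3,2
mean,graft,FRE,registration,1.94,2
sd,graft,FRE,registration,0.76,2
mean,graft,TRE_CONDYLE,registration,1.1,2
sd,graft,TRE_CONDYLE,registration,0.38,2
mean,graft,TRE_CENTER,registration,0.77,2
sd,graft,TRE_CENTER,registration,0.26,2
mean,graft,Tx_total,cbct,2.16,2
sd,graft,Tx_total,cbct,1.1,2
mean,graft,CON,cbct,2.95,2
sd,graft,CON,cbct,1.59,2
mean,graft,ANG,cbct,2.37,2
sd,graft,ANG,cbct,1.4,2
mean,graft,JUN,cbct,1.13,2
sd,graft,JUN,cbct,0.75,2
mean,graft,CON,navigation,2.41,2
sd,graft,CON,navigation,2.32,2
mean,graft,ANG,navigation,1.92,2
sd,graft,ANG,navigation,1.32,2
mean,graft,JUN,navigation,2.08,2
sd,graft,JUN,navigation,1.41,2
pearson_r,graft,CON,agreement,0.83,2
pearson_r,graft,ANG,agreement,0.74,2
pearson_r,graft,JUN,agreement,0.44,2
loa_lower,graft,CON,agreement,-3.2,1
loa_upper,graft,CON,agreement,2.1,1
loa_lower,graft,ANG,agreement,-2.4,1
loa_upper,graft,ANG,agreement,1.5,1
loa_lower,graft,JUN,agreement,-1.5,1
loa_upper,graft,JUN,agreement,3.5,1
max_abs_diff,graft,JUN,agreement,3.57,2
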