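trait,units,ms_block,ms_genotype,ms_residual,mean,min,max,cv_pct
DTP,cm,49.72,9.528,4.91,9.45,3.4,12.6,23.44
HTW,g,1.64,4554.42,0.06,133.46,31.02,201.65,0.19
LT,mm,271.82,76.12,9.28,19.46,8.82,30.81,15.65
NRT,count,0.10,0.62,0.07,5.75,5.00,6.67,4.62
NT,count,274.65,53.72,16.88,13.09,2.6,24.2,31.38
NTS,count,3230.89,504.74,306.83,39,12.93,75.67,44.91
PG,%,1736.89,1323.49,465.13,70.04,12.22,100,30.79
PH,cm,1569.56,806.06,303.21,91.77,27.8,113.33,18.97
TS,,0.21,0.36,0.06,1.37,0.98,2.45,18
WT,mm,60.94,11.33,1.45,14.22,7.96,17.22,8.48
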