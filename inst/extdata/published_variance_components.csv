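trait,sigma2_g,sigma2_p,gcv,pcv,h2
DTP,1.18,7.16,0.11,0.28,0.87
HTW,1520,1520.1,0.29,0.29,0.98
LT,20.19,35.72,0.23,0.31,0.96
NRT,0.18,0.25,0.07,0.09,0.97
NT,10.23,33.25,0.24,0.44,0.93
NTS,42.76,419.21,0.17,0.52,0.81
PG,276,771.4,0.24,0.40,0.94
PH,157.6,491,0.14,0.24,0.93
TS,0.1,0.17,0.23,0.30,0.96
WT,2.82,5.69,0.12,0.17,0.95
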