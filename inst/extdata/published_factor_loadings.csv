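trait,FA1,FA2,FA3,FA4,communality,uniqueness,psg_pct
PG,0.07,0.03,0.02,0.96,0.92,0.08,0.42
NT,-0.83,-0.11,-0.14,0.18,0.75,0.25,14.3
DTP,-0.043,-0.16,0.46,0.56,0.74,0.26,5.74
PH,-0.16,-0.26,0.04,0.90,0.90,0.10,0.96
NTS,-0.70,0.14,-0.04,-0.07,0.51,0.49,1.68
NRT,0.13,-0.08,0.73,-0.06,0.57,0.43,5.68
LT,0.02,-0.93,0.28,0.12,0.96,0.04,12.40
WT,0.01,-0.03,0.86,0.14,0.76,0.24,2.75
TS,0.04,-0.97,-0.12,0.07,0.96,0.04,8.85
HTW,-0.51,-0.53,0.39,0.22,0.75,0.25,22.80
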