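component,eigenvalue,variance_pct
PC1,3.37,33.70
PC2,1.70,17.00
PC3,1.45,14.50
PC4,1.28,12.80
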