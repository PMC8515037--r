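target_symbol,t_score
IL6,3.0
JAK3,2.5
RORC,2.0
PRKCQ,1.5
ZAP70,1.2
CCR1,2.2
CCR5,2.0
CA2,6.0
MMP1,0.3
MMP3,1.0
MMP9,1.2
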