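id,label,t0,t1,t2,t3,t4
0,0,0.12,0.54,0.33,0.21,0.08
1,1,0.98,0.11,0.07,0.45,0.77
2,0,0.25,0.61,0.40,0.18,0.05
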