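module,COL,OJI,MAR
A,22,10,7
B,13,13,16
C,0,12,12
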