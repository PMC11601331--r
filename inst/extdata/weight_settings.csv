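setting,ee,ie,ob_e,ei,ob_i,ii
A,95,410,128,58,68,180
B,94,400,128,58,66,150
C,80,450,128,68,68,220
D,95,520,95,51,42,190
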