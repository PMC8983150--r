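column,tmz_pct_of_inlet
A,99.9
B,96.4
C,82.0
D,49.8
E,18.2
F,3.3
G,0.1
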