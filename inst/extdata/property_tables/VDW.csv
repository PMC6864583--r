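element,environment,value
H,*,7.24
B,*,17.88
C,*,20.58
N,*,15.60
O,*,14.71
F,*,13.31
Si,*,38.79
P,*,24.43
S,*,24.43
Cl,*,22.45
Br,*,26.52
I,*,32.52
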