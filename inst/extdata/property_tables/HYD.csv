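element,environment,value
H,*,0.123
C,al,0.14
C,ar,0.17
C,*,0.14
N,ar,-0.40
N,*,-0.60
O,ar,0.00
O,*,-0.45
F,*,0.42
Si,*,0.50
P,*,0.31
S,ar,0.52
S,*,0.40
Cl,*,0.55
Br,*,0.77
I,*,1.05
B,*,0.20
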