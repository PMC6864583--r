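element,environment,value
H,*,1.100
B,*,3.54
C,*,2.418
N,*,1.89
O,*,1.64
F,*,0.81
Si,*,7.12
P,*,8.78
S,*,7.69
Cl,*,5.844
Br,*,8.741
I,*,13.954
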