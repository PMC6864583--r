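element,environment,value
C,*,0
H,*,0
B,*,0
F,*,0
Cl,*,0
Br,*,0
I,*,0
Si,*,0
N,sp3H0,3.24
N,sp3H1,12.03
N,sp3H2,26.02
N,sp2H0,12.36
N,sp2H1,21.94
N,sp2H2,26.02
N,sp,23.79
N,ar,12.89
N,arH,15.79
N,*,12.03
O,eth,9.23
O,OH,20.23
O,dbl,17.07
O,ar,13.14
O,*,9.23
S,thio,25.30
S,SH,38.80
S,dbl,32.09
S,ar,28.24
S,*,25.30
P,*,13.59
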