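name,a,b,x0,c,d,y0
Neg,3.949e-2,1.445e-8,6.512e+5,0,0,0
ACD,3.949e-2,1.445e-8,6.512e+5,2.694e-7,8.087e-2,2.947e-4
KIF,3.949e-2,1.445e-8,6.512e+5,1.784e-7,1.506e-1,8.382e-3
PLK,3.949e-2,1.445e-8,6.512e+5,1.337e-7,9.045e-2,2.837e-3
VHP,3.949e-2,1.445e-8,6.512e+5,2.498e-8,3.091e-7,3.458e-4
HP,3.949e-2,1.445e-8,6.512e+5,2.243e-8,1.118e-7,6.760e-4
MP,3.949e-2,1.445e-8,6.512e+5,7.258e-9,6.509e-8,2.305e-3
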