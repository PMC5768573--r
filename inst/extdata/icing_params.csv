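key,value
pG,0.006
SI,5e-4
alphaG,0.01538461538461539
alphaI,0.0017
nI,0.003
nK,0.0542
nL,0.1578
nC,0.003
VG,13.3
VI,4.0
EGP,1.16
CNS,0.3
xL,0.67
d1,0.0347
d2,0.0069
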