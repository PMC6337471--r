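delta_ct,bestkeeper,genorm,normfinder
TATA,HIS,RPL17,TATA
elF-5A,ACT2,elF-5A,elF-5A
RPL17,TUB,GAPDH,EF1a
EF1a,TATA,TATA,RPL17
GAPDH,EF1a,TUB,UBQ
UBQ,Cpn60b,UBQ,GAPDH
RA,UBQ,EF1a,TUB
GIIa,GIIa,RA,RA
TUB,elF-5A,GIIa,GIIa
HIS,GAPDH,Cpn60b,HIS
Cpn60b,RA,HIS,Cpn60b
RP,RPL17,RP,RP
AP-2,RP,AP-2,AP-2
ACT2,AP-2,ACT2,ACT2
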