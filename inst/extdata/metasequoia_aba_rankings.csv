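delta_ct,bestkeeper,genorm,normfinder
elF-5A,TATA,EF1a,TATA
EF1a,Cpn60b,TATA,EF1a
TATA,elF-5A,elF-5A,elF-5A
ACT2,EF1a,ACT2,ACT2
Cpn60b,HIS,Cpn60b,Cpn60b
RPL17,ACT2,RPL17,RPL17
RP,RPL17,RP,RP
AP-2,AP-2,AP-2,AP-2
HIS,RP,HIS,HIS
GAPDH,GAPDH,GAPDH,GAPDH
RA,RA,RA,RA
GIIa,GIIa,GIIa,GIIa
UBQ,UBQ,UBQ,UBQ
TUB,TUB,TUB,TUB
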