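delta_ct,bestkeeper,genorm,normfinder
Cpn60b,AP-2,AP-2,AP-2
EF1a,HIS,Cpn60b,Cpn60b
elF-5A,TATA,elF-5A,elF-5A
AP-2,EF1a,EF1a,GIIa
ACT2,ACT2,ACT2,EF1a
GIIa,Cpn60b,RP,ACT2
RPL17,GAPDH,GIIa,RP
RP,GIIa,RPL17,RPL17
HIS,RP,HIS,HIS
TATA,RPL17,TATA,TATA
GAPDH,elF-5A,GAPDH,GAPDH
UBQ,TUB,UBQ,UBQ
RA,UBQ,RA,RA
TUB,RA,TUB,TUB
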