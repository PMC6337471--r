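delta_ct,bestkeeper,genorm,normfinder
TATA,Cpn60b,EF1a,TATA
ACT2,GIIa,HIS,RPL17
EF1a,HIS,ACT2,ACT2
HIS,EF1a,TATA,RA
RPL17,TATA,GIIa,EF1a
RA,ACT2,Cpn60b,HIS
GIIa,GAPDH,RA,GIIa
TUB,RA,GAPDH,TUB
UBQ,elF-5A,RPL17,UBQ
Cpn60b,RPL17,UBQ,elF-5A
GAPDH,TUB,TUB,Cpn60b
elF-5A,UBQ,elF-5A,GAPDH
RP,RP,RP,RP
AP-2,AP-2,AP-2,AP-2
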