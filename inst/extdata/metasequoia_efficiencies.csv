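gene,E
ACT2,1.9807
AP-2,2.1419
Cpn60b,1.9454
EF1a,1.9384
elF-5A,2.0517
GAPDH,2.0367
GIIa,1.9042
HIS,2.0234
RA,1.9410
RP,1.8518
RPL17,1.9946
TATA,1.9278
TUB,2.0385
UBQ,1.9534
FT,1.8475
PYL8,1.9692
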