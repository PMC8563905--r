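MY
P
MB
CTX
CB
TH
HY
CNU
IRT
IRN
GRN
PARN
MDRNd
MDRNv
PGRNl
PGRNd
MARN
LRNm
NTS
SPVI
SPVO
SPVC
RM
RPA
RO
V
PC5
I5
Mes5
MEV
SUT
DCN
SC
IC
PAG
MRN
MOp
MOs
SSp
ACB
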