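ABCA4
ABHD12
BBS5
BEST1	AD
C3
CC2D2A
CDHR1
CNGB1
COL11A1	AD
FLVCR1
GRK1
GRM6
IDH3B
INPP5E
MYO7A
PRCD
PROM1	AD
PRPH2	AD
RP1	AD
WFS1
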