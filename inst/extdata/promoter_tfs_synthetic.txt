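# Illustrative promoter-bound transcription factor list (synthetic example,
# assembled for demonstration; not extracted from any database export)
SP1
HDAC1
SIN3A
MAX
MYC
GATA1
GATA2
NFKB1
RELA
JUN
FOS
STAT1
STAT3
CREB1
ATF2
E2F1
E2F4
EGR1
KLF4
NRF1
YY1
CTCF
TBP
TAF1
POLR2A
REST
USF1
USF2
ELK1
ETS1
NFYA
NFYB
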