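# Illustrative HIF1A interactor list (synthetic example for demonstration)
SP1
HDAC1
SIN3A
MAX
MYC
EP300
CREBBP
ARNT
VHL
EGLN1
HSP90AA1
TP53
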