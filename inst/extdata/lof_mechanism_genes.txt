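# Genes with an established loss-of-function disease mechanism; gates PVS1.
IRF6
PTCH1
GRHL3
TP63
CTNND1
SATB2
TBX22
CREBBP
EP300
TGFBR1
TGFBR2
SPECC1L
ECPAS
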