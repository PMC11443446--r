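# Curated genes implicated in orofacial clefting or craniofacial development.
# One symbol per line. This list is a data input to the relevance screen
# (stage a4); edit or replace it via the cohort config, not the code.
IRF6
PTCH1
GLI2
GLI3
SHH
SMO
FZD6
WNT3
WNT9B
CTNNB1
CTNND1
TGFB2
TGFB3
TGFBR1
TGFBR2
SMAD4
CREBBP
EP300
PLEKHA5
ECPAS
GRHL3
TP63
FOXE1
MSX1
BMP4
FGF8
FGFR1
FGFR2
PAX7
VAX1
SPRY2
ARHGAP29
CDH1
ESRP2
SATB2
TBX22
SPECC1L
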