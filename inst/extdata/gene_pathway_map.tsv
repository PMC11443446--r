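gene	pathway
PTCH1	HH
GLI2	HH
GLI3	HH
SHH	HH
SMO	HH
IRF6	epithelial-related
PLEKHA5	epithelial-related
GRHL3	epithelial-related
TP63	epithelial-related
ESRP2	epithelial-related
CDH1	epithelial-related
CTNND1	epithelial-related
CREBBP	TGF-beta
TGFB2	TGF-beta
TGFB3	TGF-beta
TGFBR1	TGF-beta
TGFBR2	TGF-beta
SMAD4	TGF-beta
BMP4	TGF-beta
FZD6	WNT
WNT3	WNT
WNT9B	WNT
CTNNB1	WNT
ECPAS	proteasome-associated
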