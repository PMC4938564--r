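P53_SIGNALLING	synthetic p53 signalling gene set	TP53	MDM2	MDM4	CHEK2	CCND1	CASP8	ATM	CDKN2A	CCNE1
DNA_REPAIR	synthetic DNA damage response set	BRCA2	CHEK2	EXO1	DCLRE1B	RAD51L1	ATM	MUS81
ESTROGEN_SIGNALLING	synthetic estrogen receptor set	ESR1	FGFR2	CCND1	ZMIZ1	IGFBP5
CELL_CYCLE	synthetic cell cycle set	CCND1	CDKN2A	MYC	CDCA7	CCNE1	MDM2
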