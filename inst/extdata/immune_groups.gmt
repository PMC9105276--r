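Chemokine	secreted chemotactic cytokines	CCL20	CXCL11	CCL2	CCL5	CXCL8	CXCL9	CXCL10	CXCL12
Chemokine receptor	chemokine receptors	CXCR3	CXCR4	CCR6	CCR7	ACKR3
Interferon	type I/II/III interferons	IFNG	IFNA1	IFNA2	IFNB1	IFNL1
IFN Receptor	interferon receptor subunits	IFNGR1	IFNGR2	IFNAR1	IFNAR2	IFNLR1
Interleukin	interleukins	IL32	IL33	IL6	IL1B	IL10	IL15	IL18
Interleukin receptors	interleukin receptor subunits (set A)	IL6R	IL5RA	IL2RG	IL2RA	IL7R	IL10RA	IL15RA
IL Receptors	interleukin receptor subunits (set B)	IL13RA1	IL17RA	IL17RD	IL20RA	IL4R	IL6ST	IL17RC	IL1R1
TNFSF	TNF superfamily ligands	TNFSF10	TNF	LTA	TNFSF4	CD40LG	FASLG
TNFRSF	TNF receptor superfamily	TNFRSF25	TNFRSF12A	TNFRSF11B	TNFRSF19	LTBR	TNFRSF14	TNFRSF21	TNFRSF1A	CD40	FAS
B7 family	B7 costimulatory/checkpoint family	VTCN1	ICOSLG	NCR3LG1	CD276	CD274	PDCD1LG2	CD80	CD86
BMP	bone morphogenetic proteins	BMP2	BMP4	BMP6	BMP7	GDF15
BMP Receptors	BMP/activin receptor family	BMPR1B	BMPR1A	BMPR2	ACVR1B	ACVR2A
MHC-related	MHC class I/II and accessory molecules	HLA-A	HLA-B	HLA-C	HLA-E	HLA-F	HLA-G	CD74	B2M	HLA-DPA1	HLA-DPB1	HLA-DRA	HLA-DRB1	HLA-DMA	HLA-DMB	TAP1	TAP2	NLRC5	CIITA
Complement	complement components and modulators	CLU	C3	C1QA	C1QB	CFH
Complement regulator	membrane complement regulators	CD46	CD59	CD55	SERPING1
Mucin	cell-surface mucins	MUC12	MUC1	MUC4	MUC16
Colony Stimulating Factor	colony-stimulating factors	CSF1	CSF2	CSF3
TLR	toll-like receptors	TLR5	TLR1	TLR2	TLR3	TLR4	TLR9
TGFBR	TGF-beta receptor family	TGFBR3	TGFBR1	TGFBR2
PGE2 metabolism	prostaglandin E2 synthesis and degradation	PTGS1	PTGS2	PTGES	PTGES2	PTGES3	HPGD
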