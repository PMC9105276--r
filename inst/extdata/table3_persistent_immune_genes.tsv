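# Immune-related genes abundantly expressed in both active and dormant PDX
# samples (24 dormancy-persistent genes).
family	gene	full_name
BMP Receptors	BMPR1A	Bone morphogenetic protein receptor type 1A
BMP Receptors	BMPR2	Bone morphogenetic protein receptor type 2
BMP Receptors	ACVR1B	Activin A receptor type 1B
Complement regulator	CD46	CD46 molecule
Complement regulator	CD59	CD59 molecule
MHC-related	HLA-C	Major histocompatibility complex, class I, C
IL Receptors	IL13RA1	Interleukin 13 receptor subunit alpha 1
IL Receptors	IL17RA	Interleukin 17 receptor A
IL Receptors	IL17RD	Interleukin 17 receptor D
IL Receptors	IL20RA	Interleukin 20 receptor subunit alpha
IL Receptors	IL4R	interleukin 4 receptor
IL Receptors	IL6ST	interleukin 6 signal transducer
IL Receptors	IL17RC	interleukin 17 receptor C
IL Receptors	IL1R1	interleukin 1 receptor type 1
B7 family	CD276	B7-H3
IFN Receptor	IFNGR2	interferon gamma receptor 2
IFN Receptor	IFNAR1	interferon alpha and beta receptor subunit 1
IFN Receptor	IFNGR1	interferon gamma receptor 1
TGFBR	TGFBR1	transforming growth factor beta receptor 1
TNFSF	TNFSF10	TNF superfamily member 10
TNFRSF	TNFRSF19	TNF receptor superfamily member 19
TNFRSF	LTBR	lymphotoxin beta receptor
TNFRSF	TNFRSF14	TNF receptor superfamily member 14
TNFRSF	TNFRSF21	TNF receptor superfamily member 21
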