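proliferation	synthetic placeholder proliferation signature (well-known cell-cycle markers; not the curated 131-gene set)	MKI67	PCNA	TOP2A	CCNB1	CCNA2	CDK1	CDC20	BUB1	AURKA	AURKB	PLK1	MCM2	MCM3	MCM4	MCM5	MCM6	MCM7	E2F1	FOXM1	RRM2	TYMS	BIRC5	UBE2C	KIF11	CENPF
androgen_response	synthetic placeholder androgen-responsive signature (canonical AR targets; not the curated set)	KLK3	KLK2	NKX3-1	TMPRSS2	FKBP5	NDRG1	STEAP4	ABCC4	PMEPA1	SLC45A3	ACSL3	CAMKK2	HOMER2	ZBTB16	MAF
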