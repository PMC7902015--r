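ISG_EXAMPLE	canonical interferon-stimulated genes (illustration only)	ISG15	MX1	MX2	OAS1	OAS2	OAS3	IFI6	IFI27	IFI44	IFI44L	IFIT1	IFIT3	RSAD2	SIGLEC1	USP18	LY6E	EPSTI1	HERC5	IRF7	STAT1	SERPING1	SPATS2L	PLSCR1
CELL_CYCLE_EXAMPLE	cell-cycle / proliferation genes (illustration only)	FOXM1	CCNA2	CCNB1	CCNB2	CCNE1	CDK1	CDC20	CDC45	AURKA	AURKB	PLK1	BUB1	BUB1B	MKI67	TOP2A	E2F1	E2F2	MCM2	MCM3	MCM4	MCM5	MCM6	MCM7	PCNA	RRM2	TYMS	BIRC5	KIF11	NDC80	CENPA
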