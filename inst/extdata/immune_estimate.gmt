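Immune_estimate	immune_estimate	CD3D	CD3E	CD3G	CD6	SH2D1A	TRAT1	CD8A	CD8B	GZMA	GZMB	GZMH	PRF1	KLRK1	NKG7	CD19	MS4A1	CD79A	CD79B	BLK	PTPRC	LAPTM5	CD68	CD163	CD84	MS4A4A	CD244	EOMES	PTGER4	TBX21	STAT4	IL12RB2	NCR1	KIR2DL3	XCL2	NCAM1	ITGAX	CD1C	CLEC4C	NRP1	FOXP3	IKZF2	TPSAB1	TPSB2	CPA3	MS4A2	FCGR3B	CSF3R	S100A12	CEACAM3	ICOS	CD28	CD40LG	IL2RB	ZAP70	LCK	ITK	CD27	KLRC1	KLRD1	KLRF1	NCR3	FASLG	SH2D1B	CD40	TNFRSF13B	TNFRSF13C	PAX5	BLNK	FCRL2	MARCO	MSR1	MRC1	CD86	TLR4	NOS2	ITGAL	ITGB2	SELL	CD2	CD5	PTPN22	IFNG	TNF	IL15	IL21	CSF2	LTA	CXCL9	CXCL10	CXCL11	CCL5	CCL4	CXCL13	CCR5	IL2	IL4	IL6	IL7	IL10	IL1B	IL18	C1QA	C1QB	C2	C3	C7	CFB	C5AR1
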