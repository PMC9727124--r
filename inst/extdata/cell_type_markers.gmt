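T_cells	cell_type	CD3D	CD3E	CD3G	CD6	SH2D1A	TRAT1
CD8_T_cells	cell_type	CD8A	CD8B
Cytotoxic_cells	cell_type	GZMA	GZMB	GZMH	PRF1	KLRK1	NKG7
B_cells	cell_type	CD19	MS4A1	CD79A	CD79B	BLK
CD45_cells	cell_type	PTPRC	LAPTM5
Macrophages	cell_type	CD68	CD163	CD84	MS4A4A
Exhausted_CD8	cell_type	CD244	EOMES	PTGER4
Th1_cells	cell_type	TBX21	STAT4	IL12RB2
NK_cells	cell_type	NCR1	KIR2DL3	XCL2	NCAM1
Dendritic_cells	cell_type	ITGAX	CD1C	CLEC4C	NRP1
Treg	cell_type	FOXP3	IKZF2
Mast_cells	cell_type	TPSAB1	TPSB2	CPA3	MS4A2
Neutrophils	cell_type	FCGR3B	CSF3R	S100A12	CEACAM3
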