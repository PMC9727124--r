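T_cell_function	function	ICOS	CD28	CD40LG	IL2RB	ZAP70	LCK	ITK	CD27
NK_cell_function	function	KLRC1	KLRD1	KLRF1	NCR3	FASLG	SH2D1B
B_cell_function	function	CD40	TNFRSF13B	TNFRSF13C	PAX5	BLNK	FCRL2
Macrophage_function	function	MARCO	MSR1	MRC1	CD86	TLR4	NOS2
Leukocyte_function	function	ITGAL	ITGB2	SELL	CD2	CD5	PTPN22
Cytokines	function	IFNG	TNF	IL15	IL21	CSF2	LTA
Chemokines	function	CXCL9	CXCL10	CXCL11	CCL5	CCL4	CXCL13	CCR5
Interleukins	function	IL2	IL4	IL6	IL7	IL10	IL1B	IL18
Complement	function	C1QA	C1QB	C2	C3	C7	CFB	C5AR1
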