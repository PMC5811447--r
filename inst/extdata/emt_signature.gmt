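EMT_EPITHELIAL	epithelial canonical EMT markers (TJP1 in place of OCLN)	CDH1	DSP	TJP1
EMT_MESENCHYMAL	mesenchymal canonical EMT markers	VIM	CDH2	FOXC2	SNAI1	SNAI2	TWIST1	FN1	ITGB6	MMP2	MMP3	MMP9	SOX10	GSC
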