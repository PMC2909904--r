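drug	database	rank	gene_symbol	ki_nM
Oxytocin	DrugBank	1	PREP	NA
Oxytocin	DrugBank	2	OXT	NA
Oxytocin	PDSP	3	OXTR	0.5
Oxytocin	PDSP	47	AVPR1B	1782
Oxytocin	PDSP	48	AVPR2	1544
Oxytocin	PDSP	91	AVPR1A	123
Nefazodone	DrugBank	9	HTR2A	NA
Nefazodone	DrugBank	12	SLC6A4	NA
Nefazodone	DrugBank	33	SLC6A2	NA
Nefazodone	DrugBank	267	ADRA1B	NA
Nefazodone	DrugBank	305	ADRA1A	NA
Nefazodone	PDSP	32	DRD2	910
Nefazodone	PDSP	103	SLC6A3	360
Nefazodone	PDSP	119	HTR1A	80
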