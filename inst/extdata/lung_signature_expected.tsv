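mirna_id	tumor	c_biomarker	e_biomarker	l_biomarker
hsa-miR-124-3p	lSCC	TRUE	FALSE	TRUE
hsa-miR-1304-3p	LUAD/lSCC	TRUE	FALSE	FALSE
hsa-miR-130b-3p	LUAD/lSCC	TRUE	TRUE	TRUE
hsa-miR-137	LUAD/lSCC	TRUE	FALSE	FALSE
hsa-miR-182-5p	LUAD/lSCC	TRUE	TRUE	TRUE
hsa-miR-196b-5p	LUAD/lSCC	TRUE	FALSE	TRUE
hsa-miR-203a-3p	LUAD/lSCC	TRUE	TRUE	TRUE
hsa-miR-212-3p	LUAD/lSCC	TRUE	FALSE	TRUE
hsa-miR-377-3p	LUAD/lSCC	TRUE	FALSE	FALSE
hsa-miR-449a	LUAD	TRUE	FALSE	TRUE
hsa-miR-656-3p	LUAD/lSCC	TRUE	FALSE	FALSE
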