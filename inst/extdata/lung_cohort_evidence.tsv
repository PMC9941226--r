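mirna_id	cancer_type	significant
hsa-miR-149-5p	LUAD	FALSE
hsa-miR-212-3p	LUAD	TRUE
hsa-miR-212-3p	lSCC	TRUE
hsa-miR-449a	LUAD	TRUE
hsa-miR-449a	lSCC	FALSE
hsa-miR-369-3p	LUAD	TRUE
hsa-miR-369-3p	lSCC	TRUE
hsa-miR-203a-3p	LUAD	TRUE
hsa-miR-203a-3p	lSCC	TRUE
hsa-miR-137	LUAD	TRUE
hsa-miR-137	lSCC	TRUE
hsa-miR-182-5p	LUAD	TRUE
hsa-miR-182-5p	lSCC	TRUE
hsa-miR-124-3p	lSCC	TRUE
hsa-miR-1246	lSCC	FALSE
hsa-miR-1304-3p	LUAD	TRUE
hsa-miR-1304-3p	lSCC	TRUE
hsa-miR-130b-3p	LUAD	TRUE
hsa-miR-130b-3p	lSCC	TRUE
hsa-miR-376c-3p	LUAD	TRUE
hsa-miR-376c-3p	lSCC	TRUE
hsa-miR-377-3p	LUAD	TRUE
hsa-miR-377-3p	lSCC	TRUE
hsa-miR-448	lSCC	FALSE
hsa-miR-656-3p	LUAD	TRUE
hsa-miR-656-3p	lSCC	TRUE
hsa-miR-31-5p	LUAD	TRUE
hsa-miR-31-5p	lSCC	TRUE
hsa-miR-196b-5p	LUAD	TRUE
hsa-miR-196b-5p	lSCC	TRUE
hsa-miR-196a-5p	LUAD	TRUE
hsa-miR-196a-5p	lSCC	TRUE
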