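cancer_type	mirna_id	gene_id
LUAD	hsa-miR-149-5p	SLC8A1
LUAD	hsa-miR-212-3p	MICU3
LUAD	hsa-miR-449a	CLIC5
LUAD	hsa-miR-369-3p	BMPR2
LUAD	hsa-miR-369-3p	RASSF8
lSCC	hsa-miR-203a-3p	EPB41L3
lSCC	hsa-miR-137	SLCO4C1
lSCC	hsa-miR-182-5p	ARRDC3
lSCC	hsa-miR-124-3p	AMOTL2
lSCC	hsa-miR-124-3p	ARRDC4
lSCC	hsa-miR-1246	RDX
lSCC	hsa-miR-1246	RTKN2
lSCC	hsa-miR-1304-3p	HIPK1
lSCC	hsa-miR-1304-3p	NFATC2
lSCC	hsa-miR-130b-3p	HEG1
lSCC	hsa-miR-130b-3p	PTPRG
lSCC	hsa-miR-376c-3p	CD47
lSCC	hsa-miR-376c-3p	LIMCH1
lSCC	hsa-miR-377-3p	NECAB1
lSCC	hsa-miR-377-3p	TAL1
lSCC	hsa-miR-448	MYO5B
lSCC	hsa-miR-448	REEP5
lSCC	hsa-miR-656-3p	CD55
lSCC	hsa-miR-656-3p	HHIP
lSCC	hsa-miR-31-5p	ATOH8
lSCC	hsa-miR-31-5p	CD55
lSCC	hsa-miR-31-5p	EMCN
lSCC	hsa-miR-196b-5p	BMPR2
lSCC	hsa-miR-196b-5p	RDX
lSCC	hsa-miR-196b-5p	REEP5
lSCC	hsa-miR-196b-5p	TSPAN12
lSCC	hsa-miR-196a-5p	BMPR2
lSCC	hsa-miR-196a-5p	PRTG
lSCC	hsa-miR-196a-5p	RDX
lSCC	hsa-miR-196a-5p	TMEM170B
lSCC	hsa-miR-196a-5p	TSPAN12
lSCC	hsa-miR-369-3p	ATP8A1
lSCC	hsa-miR-369-3p	IDI1
lSCC	hsa-miR-369-3p	LAMP3
lSCC	hsa-miR-369-3p	NECAB1
lSCC	hsa-miR-369-3p	PDE4D
lSCC	hsa-miR-369-3p	PREX2
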