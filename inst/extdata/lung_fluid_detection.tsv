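mirna_id	fluid	symbol
hsa-miR-369-3p	plasma	-
hsa-miR-369-3p	serum	-
hsa-miR-369-3p	exosomes	-
hsa-miR-369-3p	bronchoalveolar	+
hsa-miR-212-3p	plasma	+
hsa-miR-212-3p	serum	-
hsa-miR-212-3p	exosomes	-
hsa-miR-212-3p	bronchoalveolar	+
hsa-miR-449a	plasma	+
hsa-miR-449a	serum	-
hsa-miR-449a	exosomes	-
hsa-miR-449a	bronchoalveolar	+
hsa-miR-196a-5p	plasma	-
hsa-miR-196a-5p	serum	-
hsa-miR-196a-5p	exosomes	-
hsa-miR-196a-5p	bronchoalveolar	-
hsa-miR-31-5p	plasma	-
hsa-miR-31-5p	serum	-
hsa-miR-31-5p	exosomes	-
hsa-miR-31-5p	bronchoalveolar	+
hsa-miR-376c-3p	plasma	-
hsa-miR-376c-3p	serum	-
hsa-miR-376c-3p	exosomes	-
hsa-miR-376c-3p	bronchoalveolar	-
hsa-miR-124-3p	plasma	+
hsa-miR-124-3p	serum	-
hsa-miR-124-3p	exosomes	-
hsa-miR-124-3p	bronchoalveolar	+
hsa-miR-1304-3p	plasma	-
hsa-miR-1304-3p	serum	+
hsa-miR-1304-3p	exosomes	-
hsa-miR-1304-3p	bronchoalveolar	-
hsa-miR-137	plasma	+
hsa-miR-137	serum	-
hsa-miR-137	exosomes	-
hsa-miR-137	bronchoalveolar	-
hsa-miR-196b-5p	plasma	-
hsa-miR-196b-5p	serum	+
hsa-miR-196b-5p	exosomes	-
hsa-miR-196b-5p	bronchoalveolar	+
hsa-miR-377-3p	plasma	++
hsa-miR-377-3p	serum	-
hsa-miR-377-3p	exosomes	-
hsa-miR-377-3p	bronchoalveolar	-
hsa-miR-656-3p	plasma	++
hsa-miR-656-3p	serum	-
hsa-miR-656-3p	exosomes	-
hsa-miR-656-3p	bronchoalveolar	-
hsa-miR-130b-3p	plasma	+
hsa-miR-130b-3p	serum	+
hsa-miR-130b-3p	exosomes	+
hsa-miR-130b-3p	bronchoalveolar	+
hsa-miR-182-5p	plasma	+++
hsa-miR-182-5p	serum	+++
hsa-miR-182-5p	exosomes	++
hsa-miR-182-5p	bronchoalveolar	++
hsa-miR-203a-3p	plasma	++
hsa-miR-203a-3p	serum	++
hsa-miR-203a-3p	exosomes	++
hsa-miR-203a-3p	bronchoalveolar	+
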