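mirna_id	fluid	rpm
hsa-miR-369-3p	plasma	0
hsa-miR-369-3p	serum	2.4
hsa-miR-369-3p	exosomes	0
hsa-miR-369-3p	bronchoalveolar	44
hsa-miR-212-3p	plasma	18
hsa-miR-212-3p	serum	0
hsa-miR-212-3p	exosomes	3.1
hsa-miR-212-3p	bronchoalveolar	71
hsa-miR-449a	plasma	25
hsa-miR-449a	serum	6.8
hsa-miR-449a	exosomes	0
hsa-miR-449a	bronchoalveolar	12
hsa-miR-196a-5p	plasma	0
hsa-miR-196a-5p	serum	0
hsa-miR-196a-5p	exosomes	0
hsa-miR-196a-5p	bronchoalveolar	4.9
hsa-miR-31-5p	plasma	1.2
hsa-miR-31-5p	serum	0
hsa-miR-31-5p	exosomes	0
hsa-miR-31-5p	bronchoalveolar	96
hsa-miR-376c-3p	plasma	0
hsa-miR-376c-3p	serum	0
hsa-miR-376c-3p	exosomes	0
hsa-miR-376c-3p	bronchoalveolar	0
hsa-miR-124-3p	plasma	37
hsa-miR-124-3p	serum	8.5
hsa-miR-124-3p	exosomes	0
hsa-miR-124-3p	bronchoalveolar	59
hsa-miR-1304-3p	plasma	2.2
hsa-miR-1304-3p	serum	14
hsa-miR-1304-3p	exosomes	0
hsa-miR-1304-3p	bronchoalveolar	0
hsa-miR-137	plasma	52
hsa-miR-137	serum	0
hsa-miR-137	exosomes	0
hsa-miR-137	bronchoalveolar	7.3
hsa-miR-196b-5p	plasma	5.5
hsa-miR-196b-5p	serum	23
hsa-miR-196b-5p	exosomes	0
hsa-miR-196b-5p	bronchoalveolar	66
hsa-miR-377-3p	plasma	310
hsa-miR-377-3p	serum	0
hsa-miR-377-3p	exosomes	0
hsa-miR-377-3p	bronchoalveolar	1.8
hsa-miR-656-3p	plasma	480
hsa-miR-656-3p	serum	3.6
hsa-miR-656-3p	exosomes	0
hsa-miR-656-3p	bronchoalveolar	0
hsa-miR-130b-3p	plasma	45
hsa-miR-130b-3p	serum	28
hsa-miR-130b-3p	exosomes	63
hsa-miR-130b-3p	bronchoalveolar	90
hsa-miR-182-5p	plasma	4200
hsa-miR-182-5p	serum	1900
hsa-miR-182-5p	exosomes	540
hsa-miR-182-5p	bronchoalveolar	260
hsa-miR-203a-3p	plasma	150
hsa-miR-203a-3p	serum	700
hsa-miR-203a-3p	exosomes	120
hsa-miR-203a-3p	bronchoalveolar	33
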