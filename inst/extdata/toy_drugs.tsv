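drug_id	smiles	g1	g2	g3	g4
D01	CCO	0.5	-1.2	0.3	2.1
D02	CCN	-0.7	0.8	1.1	-0.4
D03	c1ccccc1	1.9	0.2	-0.6	0.0
D04	CC(=O)O	-1.1	-0.3	0.9	1.4
D05	CCCC	0.2	1.7	-1.8	0.6
D06	CO	0.8	-0.9	0.4	-1.5
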