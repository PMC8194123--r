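sig_id	g1	g2	g3
S01	1.0	2.0	3.0
S02	2.0	4.0	6.0
S03	0.5	0.5	0.5
S04	-1.0	0.0	1.0
S05	3.0	3.0	3.0
S06	1.5	2.5	3.5
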