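sig_id	compound_id	cell_line	is_exemplar
S01	cmpdA	PC3	1
S02	cmpdA	PC3	1
S03	cmpdB	PC3	1
S04	cmpdB	PC3	0
S05	cmpdC	MCF7	1
S06	cmpdD	MCF7	1
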