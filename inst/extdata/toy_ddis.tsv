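drug_a	drug_b	type_label
D01	D02	increased_hypoglycemia_risk
D01	D03	increased_hypoglycemia_risk
D02	D03	increased_hypoglycemia_risk
D02	D04	increased_hypoglycemia_risk
D03	D04	increased_hypoglycemia_risk
D04	D01	increased_hypoglycemia_risk
D03	D01	increased_hypoglycemia_risk
D05	D01	increased_hypoglycemia_risk
D02	D05	increased_hypoglycemia_risk
D06	D01	increased_qtc_prolongation
D02	D06	increased_qtc_prolongation
D06	D03	increased_qtc_prolongation
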