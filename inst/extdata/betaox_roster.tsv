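substrate_id	compartment	category
coa16_0	m	saturated
coa16_0_15me	m	saturated
coa26_0	x	saturated
coa16_0_15me	x	saturated
coa16_1_9z	m	unsaturated
coa18_1_9z	m	unsaturated
coa18_1_11z	m	unsaturated
coa18_2_9z12z	m	unsaturated
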