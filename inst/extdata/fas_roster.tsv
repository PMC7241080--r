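primer_id	product_length	compartment
coa2_0	16	c
coa2_0	16	m
coa4_0_3me	13	c
coa4_0_3me	13	m
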