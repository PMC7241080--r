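substrate_id	position	geometry
coa16_0	9	Z
coa18_0	9	Z
coa18_1_9z	12	Z
coa18_2_9z12z	6	Z
coa18_2_9z12z	15	Z
coa18_3_9z12z15z	6	Z
coa18_3_6z9z12z	15	Z
coa20_3_8z11z14z	5	Z
coa20_4_8z11z14z17z	5	Z
coa20_4_5z8z11z14z	17	Z
coa20_2_11z14z	8	Z
coa20_3_11z14z17z	8	Z
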