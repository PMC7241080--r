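substrate_id
coa16_0
coa18_0
coa18_1_9z
coa16_1_9z
coa18_1_11z
coa18_2_9z12z
coa18_3_6z9z12z
coa18_3_9z12z15z
coa20_4_5z8z11z14z
coa20_5_5z8z11z14z17z
coa14_0
coa16_0_15me
coa14_0_13me
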