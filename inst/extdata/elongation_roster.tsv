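start_id	end_length
coa10_0	12
coa12_0	14
coa14_0	16
coa16_0	18
coa18_0	20
coa20_0	22
coa22_0	24
coa24_0	26
coa12_0_11me	15
coa14_0_13me	17
coa16_1_9z	18
coa18_1_11z	20
coa18_1_9z	20
coa20_1_11z	22
coa22_1_13z	24
coa24_1_15z	26
coa18_2_9z12z	20
coa18_3_6z9z12z	20
coa18_3_9z12z15z	20
coa18_4_6z9z12z15z	20
coa20_4_5z8z11z14z	22
coa20_5_5z8z11z14z17z	22
coa22_4_7z10z13z16z	24
coa22_5_7z10z13z16z19z	24
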