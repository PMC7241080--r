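fa_id
fa4_0
fa6_0
fa8_0
fa10_0
fa12_0
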