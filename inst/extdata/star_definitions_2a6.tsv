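cyp	allele	defining_variants
2A6	*36	rs5031016
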