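# oborel-instances v1
instance	a1	EX:A
instance	a2	EX:A
instance	b1	EX:B
link	part_of	a1	b1
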