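format-version: 1.2

[Term]
id: EX:A
name: part class
relationship: part_of EX:B
property_value: oborel:kind MATERIAL

[Term]
id: EX:B
name: whole class
property_value: oborel:kind MATERIAL
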