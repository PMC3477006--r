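format-version: 1.2
ontology: xao-fragment

[Term]
id: XAO:FIX01
name: Xenopus Developmental Stage
property_value: oborel:kind PROCESS

[Term]
id: XAO:FIX02
name: Unfertilized Egg
is_a: XAO:FIX01
property_value: oborel:kind PROCESS

[Term]
id: XAO:FIX03
name: Embryonic Stage
is_a: XAO:FIX01
property_value: oborel:kind PROCESS

[Term]
id: XAO:FIX04
name: Adult
is_a: XAO:FIX01
property_value: oborel:kind PROCESS

[Term]
id: XAO:FIX05
name: Death
is_a: XAO:FIX01
property_value: oborel:kind PROCESS

[Term]
id: XAO:FIX06
name: Blastula
is_a: XAO:FIX03
property_value: oborel:kind PROCESS

[Term]
id: XAO:FIX07
name: Neurula
is_a: XAO:FIX03
property_value: oborel:kind PROCESS

[Term]
id: XAO:FIX08
name: NF Stage 7
relationship: part_of XAO:FIX06
property_value: oborel:kind PROCESS

[Term]
id: XAO:FIX09
name: NF Stage 8
relationship: part_of XAO:FIX06
relationship: preceded_by XAO:FIX08
property_value: oborel:kind PROCESS

[Term]
id: XAO:FIX10
name: NF Stage 9
relationship: part_of XAO:FIX06
relationship: preceded_by XAO:FIX09
property_value: oborel:kind PROCESS
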