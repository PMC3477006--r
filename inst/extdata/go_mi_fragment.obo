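format-version: 1.2
ontology: go-mi-fragment

[Term]
id: GO:MI01
name: Developmental Process
property_value: oborel:kind PROCESS

[Term]
id: GO:MI02
name: Cellular Process
property_value: oborel:kind PROCESS

[Term]
id: GO:MI03
name: Cellular Developmental Process
is_a: GO:MI01
is_a: GO:MI02
property_value: oborel:kind PROCESS

[Term]
id: GO:MI04
name: Cell Communication
property_value: oborel:kind PROCESS

[Term]
id: GO:MI05
name: Signaling
property_value: oborel:kind PROCESS

[Term]
id: GO:MI06
name: Cell-Cell Signaling
is_a: GO:MI04
is_a: GO:MI05
property_value: oborel:kind PROCESS

[Term]
id: GO:MI07
name: Cell Fate Commitment
property_value: oborel:kind PROCESS

[Term]
id: GO:MI08
name: Cell-Cell Signaling Involved in Cell Fate Commitment
is_a: GO:MI06
relationship: part_of GO:MI07
property_value: oborel:kind PROCESS
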