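format-version: 1.2
ontology: go-root-fragment

[Term]
id: GO:FIX01
name: Gene Ontology

[Term]
id: GO:FIX02
name: Biological Process
is_a: GO:FIX01
property_value: oborel:kind PROCESS

[Term]
id: GO:FIX03
name: Cellular Component
is_a: GO:FIX01
property_value: oborel:kind CONTINUANT

[Term]
id: GO:FIX04
name: Molecular Function
is_a: GO:FIX01
property_value: oborel:kind PROCESS
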