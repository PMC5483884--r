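format-version: 1.2
ontology: radiation-response-snapshot
remark: Minimal snapshot of the radiation-response sub-hierarchy used by the biomarker screen. One synthetic obsolete term and one synthetic alt_id are included to exercise reader semantics.

[Term]
id: GO:0009314
name: response to radiation

[Term]
id: GO:0010212
name: response to ionizing radiation
is_a: GO:0009314

[Term]
id: GO:0010165
name: response to X-ray
is_a: GO:0010212

[Term]
id: GO:0010332
name: response to gamma radiation
alt_id: GO:7010332
is_a: GO:0010212

[Term]
id: GO:0009411
name: response to UV
is_a: GO:0009314

[Term]
id: GO:0070141
name: response to UV-A
is_a: GO:0009411

[Term]
id: GO:0010224
name: response to UV-B
is_a: GO:0009411

[Term]
id: GO:0010225
name: response to UV-C
is_a: GO:0009411

[Term]
id: GO:7000001
name: obsolete synthetic UV response term
is_obsolete: true
is_a: GO:0009411
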