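format-version: 1.2
ontology: dna-repair-snapshot
remark: Minimal snapshot of the DNA repair sub-hierarchy used by the cross-kingdom comparison. HR and NHEJ descend from DNA repair through the intermediate double-strand break repair term.

[Term]
id: GO:0006281
name: DNA repair

[Term]
id: GO:0006284
name: base-excision repair
is_a: GO:0006281

[Term]
id: GO:0006289
name: nucleotide-excision repair
is_a: GO:0006281

[Term]
id: GO:0006298
name: mismatch repair
is_a: GO:0006281

[Term]
id: GO:0006302
name: double-strand break repair
is_a: GO:0006281

[Term]
id: GO:0000724
name: double-strand break repair via homologous recombination
is_a: GO:0006302

[Term]
id: GO:0006303
name: double-strand break repair via non-homologous end joining
is_a: GO:0006302
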