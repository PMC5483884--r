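# Per-mechanism counts from the cross-kingdom comparison: annotated genes per
# taxon, genes with at least one orthologue in the other taxon, the
# orthologue-coverage percentages (half-up, one decimal), and the counts of
# suggested new genes.
mechanism	go_term	n_hs	n_hs_orth	pct_hs	n_at	n_at_orth	pct_at	new_hs	new_at
DNA repair	GO:0006281	507	259	51.1	300	185	61.7	86	243
BER	GO:0006284	52	32	61.5	29	12	41.4	3	36
NER	GO:0006289	124	59	47.6	30	21	70.0	5	57
MMR	GO:0006298	43	14	32.6	17	12	70.6	0	1
HR	GO:0000724	162	76	46.9	50	37	74.0	38	87
NHEJ	GO:0006303	73	9	12.3	7	4	57.1	0	8
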