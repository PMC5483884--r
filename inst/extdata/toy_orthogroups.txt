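# Six-group orthogroup toy over a human (hsa) and a plant (ath) taxon.
# Genes annotated for the mechanism under study: hsa a, b, d, e; ath ii, iii.
# Groups A-C contain both taxa, D and E only plant genes, F only human genes.
# Asserted relations: (a, ii) paired through group B; ath gene i inferred new
# in group A; hsa gene c inferred new in group C; ath gene iv reached through
# the second hop via group D; group F (hence hsa gene e) excluded.
# The membership of groups B, C and E beyond those relations is a synthetic
# completion.
A: hsa|a ath|i
B: hsa|a hsa|b ath|ii
C: hsa|c hsa|d ath|iii
D: ath|ii ath|iv
E: ath|v
F: hsa|e
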