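# orthoscreen

Orthology-based screening of radiation-response and DNA-repair gene sets.

## What problem this solves

Plants are being explored as living radiation dosimeters: a panel of genes
whose induction is specific to one radiation quality (X-ray, γ-ray, UV-A,
UV-B or UV-C) would let a sessile "biosensor plant" report what kind of
radiation its habitat receives. Finding such a panel, and relating it to the
human DNA damage response, is an exercise in comparative functional
genomics over heterogeneous public resources: the Gene Ontology, per-species
GO annotation sets, pairwise orthologue calls, OrthoMCL-style orthogroups
and STRING-style protein–protein interaction networks.

`orthoscreen` implements that screen as a reproducible, file-based pipeline
for computational biologists. All inputs are snapshots (OBO, GAF/TSV,
orthologue-map TSV, OrthoMCL groups format, edge-list TSV); no live database
is queried. A seeded synthetic-corpus module generates inputs with planted
ground truth, so every stage is testable offline.

## The two analyses

**Radiation-biomarker screen** (`run_biodosimeter()`):

1. *Ontology*: load an OBO snapshot, compute the iterated child-term closure
   of `response to radiation` (GO:0009314) over `is_a`/`part_of`, and
   validate a curated selection of quality-specific terms (UV-A/B/C, X-ray,
   γ-ray and their parents).
2. *Projection*: for each of the plant species (39 in the reference
   configuration, model plant included), map every annotated gene to its
   *Arabidopsis thaliana* counterpart through the orthologue map and unify
   per category. The species multiplicity of a reference gene g in category
   c is
   `m(g, c) = |{ species s : some orthologue of g in s is annotated to c }|`.
3. *Exclusivity*: partition the category→gene-set family into its full
   2^k − 1 Venn cells; a biomarker must be **exclusive**, i.e. annotated to
   exactly one leaf radiation quality. Genes in several leaf qualities are
   discarded; genes only under parent terms are reported separately.
4. *Network*: on the score-thresholded interaction graph (default
   `combined_score >= 400`), score each node by the number of cliques of
   size ≥ 3 containing it ("dense-clique nodes") and shortlist the top
   scorers per category.
5. *Ranking*: order the shortlist by multiplicity, then clique score, then
   gene id; optionally resolve each candidate to human counterparts via
   protein-level orthogroups.

**Cross-kingdom repair comparison** (`run_repair_comparison()`): for each
DNA-repair mechanism (DNA repair, BER, NER, MMR, HR, NHEJ), take the
annotated gene sets of the two taxa and scan every orthogroup containing an
annotated gene. In a group with members of both taxa, annotated genes are
paired as orthologues and unannotated members become candidate **genes in
new roles** for that mechanism; a single second hop through an annotated
gene's other groups widens the candidate set; groups lacking the other
taxon are excluded. The summary reports, per mechanism, how many annotated
genes have an orthologue in the other taxon (as a half-up one-decimal
percentage) and how many new genes were inferred.

## Worked example

The packaged six-group toy (`toy_transfer_fixture()`) has human genes a, b, d, e and
plant genes ii, iii annotated under the mechanism; groups A–C span both
taxa, D–E are plant-only, F is human-only:

```r
library(orthoscreen)
fx <- toy_transfer_fixture()
res <- transfer(fx$annotated_A, fx$annotated_B, fx$groups,
                "hsa", "ath", expansion_depth = 1, mechanism = "DNA repair")
res
#> transfer_result [DNA repair] : 3 pairs; 1 new hsa genes; 1 new ath genes;
#>   1 expansion candidates; 2 excluded groups
res$pairs
#>   gene_A gene_B
#> 1      a     ii
#> 2      b     ii
#> 3      d    iii
res$new_A; res$new_B
#> [1] "c"
#> [1] "i"
res$expansion_new
#>   taxon gene
#> 1   ath   iv
```

The annotated pair (a, ii) co-occurs in group B; the plant gene i is
inferred new from group A and the human gene c from group C; iv is only
reached by the second hop (through ii's plant-only group D); group F has no
plant member, so it is excluded and the annotated human gene e is never
paired. The per-mechanism summary turns this into counts and coverage
percentages:

```r
summarize_transfers(list(res),
                    data.frame(mechanism = "DNA repair", n_A = 4, n_B = 2))
#>    mechanism n_A n_A_with_orth pct_A n_B n_B_with_orth pct_B n_new_A n_new_B
#> 1 DNA repair   4             3    75   2             2   100       1       1
```

Three of the four annotated human genes (75%) and both plant genes (100%)
have an orthologue in the other taxon, and one new gene is proposed per
taxon.

## Package layout

- `R/ontology.R` — OBO reader, descendant closure, curated-selection checks
- `R/projection.R` — annotation loading (TSV/GAF), orthologue projection,
  multiplicity, ranking
- `R/setops.R` — Venn partition and exclusivity filtering
- `R/network.R` — edge-list loading, clique-participation scores, hub
  shortlisting
- `R/transfer.R` — orthogroup parsing/classification, annotation transfer,
  counterpart lookup, per-mechanism summaries
- `R/synthetic.R` — seeded corpus generators with planted truth; packaged
  fixtures
- `R/pipelines.R` — config-driven end-to-end drivers
- `vignettes/orthoscreen-methods.Rmd` — model, assumptions, parameter and
  design rationale
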