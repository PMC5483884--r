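---
title: "orthoscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orthoscreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoscreen)
```

This vignette explains what each stage of the pipeline computes, the
assumptions behind it, the parameters that matter, and the design choices
made where the procedure was genuinely open. The package addresses two
linked questions: which plant genes could serve as radiation-quality-specific
biomarkers, and how the DNA-repair gene complements of human and
*Arabidopsis thaliana* relate through orthology.

## Ontology stage

The ontology is modelled as a DAG of terms with typed child→parent edges
(`is_a`, `part_of`, `regulates`, `other`), read from an OBO 1.2/1.4
snapshot. `descendants()` computes the least fixed point of repeated
direct-child expansion — the programmatic equivalent of iteratively asking a
GO browser for direct descendants until nothing new appears.

Choices worth noting:

* **Relation subset.** The default closure follows `is_a` and `part_of`,
  the ancestry convention of mainstream GO browsers; it is configurable
  because different browsers traverse different relation sets. Restricting
  the relation set can only shrink the closure (tested as a monotonicity
  property).
* **Obsolete terms** are excluded from closures by default: they carry no
  annotations, so including them could only inject dead identifiers into
  the projection. `include_obsolete = TRUE` is available for audits.
* **Term normalization.** Ids are upper-cased and zero-padded to the
  canonical `GO:` + 7-digit form; `alt_id`s resolve to their canonical term
  before any lookup, so a selection written with superseded accessions
  still validates.
* **Curated selection, not automatic pruning.** Which descendant terms are
  "sufficient" for a screen is a curatorial judgement (annotation density,
  specificity, assay relevance), not a graph property; `select_terms()`
  therefore validates a curated list against the hierarchy and reports the
  descendants not covered by any selected term's closure, rather than
  trying to derive the selection itself.

## Projection stage

Annotations arrive per species as (species, term, gene) triples, either
from a 3-column TSV or from GAF 2.x (rows with a `NOT` qualifier are
dropped — a negated annotation must not seed a biomarker). Each species'
genes are mapped to the reference plant through its pairwise orthologue
map; the reference species participates through the implied identity map.
Orthology is treated as many-to-many, as orthologue calls from genome
databases generally are: every reference counterpart of a source gene
receives a provenance record. Source genes with no counterpart are dropped
but tallied, because silent loss would bias multiplicity downward
invisibly.

**Multiplicity counts species, not orthologue genes**: a species
contributing three in-paralogues to the same reference gene is one
independent observation of conservation, not three. Candidate ranking sorts
by multiplicity (descending), then network score (descending), then gene id
(ascending); the final key exists purely to make output deterministic.

## Exclusivity stage

The projected category→gene-set family is decomposed into its full
$2^k - 1$ Venn cells by per-gene membership bitmask, which scales past the
5–6-category limit of diagram-drawing tools. A biomarker for radiation
quality must be **exclusive**: annotated to exactly one leaf quality
(X-ray, γ-ray, UV-A, UV-B, UV-C). Parent categories (response to UV,
response to ionizing radiation) are deliberately kept out of the
exclusivity test — a gene annotated to UV-B and to the generic UV parent is
still a UV-B-specific candidate — but genes found *only* under parent terms
are reported as a separate `parent_only` channel rather than being silently
discarded or silently admitted. Gene ids are compared by exact string
equality after whitespace trimming, preserving case (AGI locus codes are
case-significant by convention).

## Network stage

"Nodes of dense cliques" is operationalized as a clique-participation
count: on the graph restricted to edges with `combined_score >= min_score`
(default 400, the conventional medium-confidence cut on the 0–1000 score
scale), each node's score is the number of **all** cliques of size
`min_size` or larger (default 3) that contain it. Counting all cliques
rather than only maximal ones makes the score monotone under edge addition
and directly oracle-checkable by subset enumeration; a member of one K5
scores $\binom{4}{2} + \binom{4}{3} + \binom{4}{4} = 11$. The weighted
degree (incident score sum / 1000) breaks ties. Enumeration is guarded by a
cap on the number of maximal cliques (default $10^5$) so a pathological
input fails fast instead of hanging. Scores stay on the integer 0–1000
scale at I/O so input files round-trip bit-exactly.

How many candidates to keep per category (`top_n`) is an explicit
configuration input: it is a screening-budget decision, not a property of
the data.

## Transfer stage

The transfer algorithm is the package's core. Annotated gene sets for a
mechanism are given for two taxa; orthogroups are scanned starting from the
annotated genes, and within every reached group that contains members of
both taxa:

* annotated genes of taxon A × annotated genes of taxon B become
  **orthologue pairs** for the mechanism;
* unannotated members of either taxon become **candidate new genes** —
  genes plausibly acting in the mechanism by virtue of shared ancestry with
  genes known to act in it.

A reached group whose members cover only one of the two taxa is recorded
as **excluded**: it can support neither pairing nor cross-taxon inference.
Groups never reached by any annotated gene are inert — the scan is
query-driven, so a group no query leads to contributes nothing.

With `expansion_depth = 1`, one further hop is taken: each annotated gene's
groups (single-taxon groups included) are scanned once, and their
unannotated same-taxon members join the candidate list as `expansion_new`
(genes already inferred in the first pass are not repeated). Depth is
capped at one hop by design: orthogroup membership is transitively dense,
and an unbounded closure would flood-fill the orthology graph, destroying
the interpretability of "reached from a characterized gene in one step".

Counterpart lookup (`find_counterpart_orthologs()`) works at the protein
level — orthogroup databases cluster proteins — and collapses isoforms back
to gene symbols at the end: a counterpart relation holds between genes if
any protein of one shares a group with any protein of the other.

"New" status is per mechanism: a gene well known in base-excision repair
can still be newly proposed for homologous recombination; the summaries
therefore count new genes within each mechanism independently.

### Summary percentages

Per mechanism, the summary reports how many annotated genes of each taxon
have at least one orthologue in the other, as a percentage rounded
**half-up to one decimal** (base R's banker's rounding would turn e.g.
6.25 into 6.2; half-up reproduces conventional reporting). Two counting
rules are provided: the default `"pair"` rule credits a gene only if it
appears in an actual orthologue pair; the `"group"` alternative credits any
annotated gene sitting in a both-taxa group even when the other taxon's
members there are unannotated. The pair rule is the default because the
summary's column is glossed as genes *that have orthologues* among the
characterized sets; the group rule is retained as a documented alternative
since the distinction is invisible in most groups and material in a few.

## Synthetic corpora

The generators produce inputs with the structure the analysis assumes and a
recorded planted truth, so recovery can be asserted exactly:

* `gen_go_dag()` — a rooted tree plus sparse extra child→ancestor edges
  (a genuine DAG, as GO is), fully seed-deterministic.
* `gen_projection_corpus()` — the default specification mirrors the
  reference screen: **39 species** (reference included), the **seven**
  radiation-quality terms, and a reference pool of **410 genes**. The
  remaining rates are not dictated by the screen's configuration and were
  fixed once at values realistic for plant genome annotation: an
  `annotation_rate` of 0.5 (GO coverage outside model species is sparse),
  `cross_category_overlap` of 0.1 (a minority of radiation-response genes
  respond to several qualities — this is exactly why the exclusivity filter
  exists), and `orthology_retention` of 0.95 (a few percent of genes lack a
  called counterpart). Every (species, term) list is guaranteed non-empty,
  so a corpus always yields species × terms annotation sets (273 under the
  defaults).
* `gen_orthogroup_corpus()` — both-taxa groups seeded with annotated genes,
  single-taxon groups to exercise the exclusion channel, and a configurable
  number of planted unannotated genes placed only in both-taxa groups, so
  zero-noise transfer recovers them with precision = recall = 1.
* `gen_ppi()` — planted cliques fully wired at score 999 over
  Bernoulli(`background_p`) background edges at score 500.

What the synthetic corpora do **not** emulate: real annotation-evidence
heterogeneity (IEA vs experimental codes), phylogenetic correlation between
species (each species samples independently), sequence-level orthology
error, and the heavy-tailed degree distribution of real interaction
networks. Passing recovery tests therefore demonstrates the algorithms'
correctness on structurally faithful inputs, not robustness to every
artefact of real resources.

All generators derive independent RNG streams from a single corpus seed and
restore the caller's RNG state, so reruns are byte-identical and
test-order-independent.

## Numerical and degenerate-input conventions

* All output tables are sorted on documented keys; reruns are
  byte-identical.
* Duplicate undirected edges collapse to the maximum score; self-loops are
  dropped.
* Empty inputs propagate as empty, never as errors: an empty annotation
  set yields an all-zero summary; an edgeless graph yields all-zero clique
  scores; an empty OBO body yields an empty DAG.
* Validation failures (cyclic hierarchies, duplicate group ids, malformed
  rows) raise errors naming the offending element or line.

## Problem sizes used in the test suite

The oracle-equivalence suites run at sizes where brute force is exact and
fast: DAGs up to ~40 terms against boolean-matrix reachability, Venn
families of 4–5 categories × 50–100 genes against per-gene bitmask
classification, 12-node graphs against full subset enumeration (all
$2^{12}$ vertex subsets), and transfer against an exhaustive triple scan
over 30–40 groups and up to 100 genes. The planted-clique recovery rate is
estimated over 100 seeds at 40 nodes and background density 0.05. These
sizes were chosen so each suite gives exact, reproducible verdicts at
desk scale.

## Known limitations

* The OBO reader covers the stanza fields this pipeline consumes; it is not
  a general OWL/OBO reasoner (no cross-products, no property chains).
* Orthology is consumed, never inferred: the quality of projection and
  transfer is bounded by the snapshot's orthologue calls.
* Headline corpus totals from any particular database era (numbers of
  retrieved terms, projected genes, inferred new genes) are
  snapshot-dependent by nature; the package reproduces the procedure and
  its in-corpus arithmetic, not a specific database vintage.
* Clique counting is exponential in the worst case; the maximal-clique cap
  makes the failure mode explicit rather than open-ended.
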