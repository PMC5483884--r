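make_selection <- function(cats, terms) {
  dag <- orthoscreen:::radiation_dag_for(cats, setNames(terms, cats))
  select_terms(dag$dag, dag$root,
               data.frame(term_id = terms, category = cats))
}

test_that("TSV and GAF annotation dialects load as expected", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species\tterm_id\tgene_id",
               "spA\tGO:0010224\tg1",
               "spB\tGO:0010224\tg2",
               "spA\tGO:0010224\tg3"), tsv)
  ann <- load_annotations(tsv, dialect = "tsv")
  expect_equal(nrow(ann), 3)
  expect_equal(n_annotation_sets(ann), 2)  # one set per (species, term)

  gaf <- withr::local_tempfile(fileext = ".gaf")
  row <- function(gene, qual) paste(
    c("TAIR", gene, gene, qual, "GO:0010224", "TAIR:1", "IEA", "", "P",
      "", "", "gene", "taxon:3702", "20160101", "TAIR", "", ""),
    collapse = "\t")
  writeLines(c("!gaf-version: 2.1", row("AT1G01010", ""),
               row("AT1G01020", "NOT"), row("AT1G01030", "colocalizes_with")),
             gaf)
  ann2 <- load_annotations(gaf, dialect = "gaf")
  expect_setequal(ann2$gene_id, c("AT1G01010", "AT1G01030"))  # NOT row dropped
  expect_equal(unique(ann2$species), "3702")
})

test_that("projection unions mapped genes with full provenance", {
  sel <- make_selection("UV-B", "GO:0010224")
  ann <- data.frame(species = c("spA", "spB"), term_id = "GO:0010224",
                    gene_id = c("g1", "g2"))
  maps <- data.frame(species = c("spA", "spB"),
                     source_gene = c("g1", "g2"),
                     reference_gene = c("R1", "R1"))
  proj <- project_to_reference(ann, maps, "ref", sel)
  expect_equal(unique(proj$reference_gene), "R1")
  expect_equal(nrow(proj), 2)              # two provenance records
  expect_setequal(proj$species, c("spA", "spB"))
  expect_equal(attr(proj, "dropped"), 0)
})

test_that("the reference species projects through the identity map", {
  sel <- make_selection("UV-B", "GO:0010224")
  ann <- data.frame(species = "ref", term_id = "GO:0010224", gene_id = "R9")
  proj <- project_to_reference(ann, data.frame(species = character(),
                                               source_gene = character(),
                                               reference_gene = character()),
                               "ref", sel)
  expect_equal(proj$reference_gene, "R9")
  expect_equal(proj$source_gene, "R9")
})

test_that("unmapped source genes are dropped and tallied; unmapped species error", {
  sel <- make_selection("UV-B", "GO:0010224")
  ann <- data.frame(species = c("spA", "spA"), term_id = "GO:0010224",
                    gene_id = c("g1", "g_lost"))
  maps <- data.frame(species = "spA", source_gene = "g1",
                     reference_gene = "R1")
  proj <- project_to_reference(ann, maps, "ref", sel)
  expect_equal(attr(proj, "dropped"), 1)
  expect_equal(proj$reference_gene, "R1")

  ann2 <- data.frame(species = "spZ", term_id = "GO:0010224", gene_id = "g")
  expect_error(project_to_reference(ann2, maps, "ref", sel),
               "no orthologue map")
})

test_that("many-to-many orthology credits every reference counterpart", {
  sel <- make_selection("UV-B", "GO:0010224")
  ann <- data.frame(species = "spA", term_id = "GO:0010224", gene_id = "g1")
  maps <- data.frame(species = "spA", source_gene = c("g1", "g1"),
                     reference_gene = c("R1", "R2"))
  proj <- project_to_reference(ann, maps, "ref", sel)
  expect_setequal(proj$reference_gene, c("R1", "R2"))
})

test_that("multiplicity counts distinct species, not orthologue genes", {
  proj <- structure(
    data.frame(category = "UV-B", reference_gene = "R1",
               species = c("s1", "s1", "s3"),
               source_gene = c("a", "b", "c")),
    class = c("projected_annotation", "data.frame"))
  m <- multiplicity(proj)
  expect_equal(m$multiplicity, 2)

  empty <- structure(
    data.frame(category = character(), reference_gene = character(),
               species = character(), source_gene = character()),
    class = c("projected_annotation", "data.frame"))
  expect_equal(nrow(multiplicity(empty)), 0)
})

test_that("the packaged multiplicity table carries the curated species counts", {
  tab <- read.delim(ext_fixture("biomarker_multiplicity.tsv"), comment.char = "#")
  expect_equal(tab$multiplicity[tab$gene == "RAD54"], 30)
  expect_equal(max(tab$multiplicity[tab$category == "UV-B"]), 32)
  expect_equal(nrow(tab), 26)
})

test_that("candidate ranking follows multiplicity, score, then gene id", {
  proj <- structure(
    data.frame(category = "c",
               reference_gene = rep(c("x", "y", "z"), times = c(5, 9, 9)),
               species = c(paste0("s", 1:5), paste0("s", 1:9),
                           paste0("s", 1:9)),
               source_gene = "src"),
    class = c("projected_annotation", "data.frame"))
  r <- rank_candidates(proj, c(x = 1, y = 0, z = 5), c("x", "y", "z"))
  # y and z tie on multiplicity 9; z wins on node score
  expect_equal(r$reference_gene, c("z", "y", "x"))

  expect_warning(
    r2 <- rank_candidates(proj, numeric(), c("x", "ghost")),
    "absent from projection")
  expect_equal(r2$reference_gene[nrow(r2)], "ghost")
  expect_equal(r2$multiplicity[nrow(r2)], 0)
})

test_that("ranking equals an independent full sort on a seeded instance", {
  set.seed(42)
  genes <- sprintf("G%02d", 1:20)
  rows <- do.call(rbind, lapply(genes, function(g) {
    k <- sample(1:8, 1)
    data.frame(category = "c", reference_gene = g,
               species = sprintf("s%02d", sample(1:10, k)),
               source_gene = "src")
  }))
  proj <- structure(rows, class = c("projected_annotation", "data.frame"))
  scores <- setNames(round(runif(20), 3), genes)
  got <- rank_candidates(proj, scores, genes)

  mult <- sapply(genes, function(g)
    length(unique(rows$species[rows$reference_gene == g])))
  oracle <- data.frame(gene = genes, mult = mult, score = scores[genes])
  oracle <- oracle[order(-oracle$mult, -oracle$score, oracle$gene), ]
  expect_equal(got$reference_gene, oracle$gene)
})

test_that("projection conserves provenance and is monotone in species", {
  corp <- gen_projection_corpus(default_corpus_spec(seed = 5))
  proj <- project_to_reference(corp$annotations, corp$maps, "Athaliana",
                               corp$selection)
  # every mappable (species, source gene, term) triple appears as provenance
  oth <- corp$annotations[corp$annotations$species != "Athaliana", ]
  mappable <- merge(oth, corp$maps,
                    by.x = c("species", "gene_id"),
                    by.y = c("species", "source_gene"))
  n_expected <- nrow(unique(mappable[, c("species", "gene_id", "term_id",
                                         "reference_gene")])) +
    nrow(unique(corp$annotations[corp$annotations$species == "Athaliana", ]))
  expect_equal(nrow(proj), n_expected)

  # removing one species never raises any multiplicity
  sp <- setdiff(unique(corp$annotations$species), "Athaliana")[1]
  ann_less <- corp$annotations[corp$annotations$species != sp, ]
  proj_less <- project_to_reference(ann_less, corp$maps, "Athaliana",
                                    corp$selection)
  m_full <- multiplicity(proj)
  m_less <- multiplicity(proj_less)
  merged <- merge(m_less, m_full, by = c("category", "reference_gene"))
  expect_true(all(merged$multiplicity.x <= merged$multiplicity.y))
})
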