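test_that("orthogroup files parse, round-trip, and reject malformed input", {
  f <- tempfile()
  writeLines("OG1: hsa|P1 ath|Q1", f)
  g <- load_orthogroups(f)
  expect_equal(nrow(g), 2)
  expect_setequal(g$taxon, c("hsa", "ath"))

  writeLines(character(), f)
  expect_equal(nrow(load_orthogroups(f)), 0)

  writeLines(c("OG1: hsa|P1", "no colon here"), f)
  expect_error(load_orthogroups(f), "line 2.*missing ':'")
  writeLines(c("OG1: hsa|P1", "OG2: badmember"), f)
  expect_error(load_orthogroups(f), "expected taxon\\|gene")
  writeLines(c("OG1: hsa|P1", "OG1: ath|Q1"), f)
  expect_error(load_orthogroups(f), "duplicate group id")

  # write/read round-trip is byte-identical
  fx <- toy_transfer_fixture()
  out1 <- tempfile(); out2 <- tempfile()
  write_orthogroups(fx$groups, out1)
  write_orthogroups(load_orthogroups(out1), out2)
  expect_identical(readLines(out1), readLines(out2))
})

test_that("the packaged six-group toy has the stated taxon composition", {
  fx <- toy_transfer_fixture()
  expect_setequal(unique(fx$groups$group_id), LETTERS[1:6])
  cls <- classify_groups(fx$groups, "hsa", "ath")
  expect_equal(unname(cls[c("A", "B", "C")]), rep("both", 3))
  expect_equal(unname(cls[c("D", "E")]), rep("B_only", 2))
  expect_equal(unname(cls["F"]), "A_only")
})

test_that("group classification matches a membership oracle on random tables", {
  set.seed(77)
  g <- random_groups(100, 40)
  cls <- classify_groups(g, "hsa", "ath")
  for (id in unique(g$group_id)) {
    m <- g[g$group_id == id, ]
    want <- if (any(m$taxon == "hsa") && any(m$taxon == "ath")) "both"
            else if (any(m$taxon == "hsa")) "A_only"
            else if (any(m$taxon == "ath")) "B_only" else "neither"
    expect_equal(unname(cls[id]), want)
  }
  expect_error(classify_groups(g, "hsa", "hsa"), "distinct")
})

test_that("the worked toy example transfers as described", {
  fx <- toy_transfer_fixture()
  r <- transfer(fx$annotated_A, fx$annotated_B, fx$groups,
                fx$taxon_A, fx$taxon_B, expansion_depth = 1)
  # the characterized genes a and ii are paired through group B
  expect_true(any(r$pairs$gene_A == "a" & r$pairs$gene_B == "ii"))
  # the plant gene i is inferred new through group A
  expect_true("i" %in% r$new_B)
  # the human gene c is inferred new through a both-taxa group
  expect_true("c" %in% r$new_A)
  # the plant gene iv is only reached by the second hop
  expect_true(any(r$expansion_new$taxon == "ath" &
                    r$expansion_new$gene == "iv"))
  # group F contains no plant gene: excluded, so gene e is never paired
  expect_true("F" %in% r$excluded_groups)
  expect_false("e" %in% r$pairs$gene_A)

  r0 <- transfer(fx$annotated_A, fx$annotated_B, fx$groups,
                 fx$taxon_A, fx$taxon_B, expansion_depth = 0)
  expect_equal(nrow(r0$expansion_new), 0)
  expect_error(transfer(fx$annotated_A, fx$annotated_B, fx$groups,
                        fx$taxon_A, fx$taxon_B, expansion_depth = 2),
               "expansion_depth")
})

test_that("swapping the taxa transposes the result exactly", {
  fx <- toy_transfer_fixture()
  r <- transfer(fx$annotated_A, fx$annotated_B, fx$groups,
                fx$taxon_A, fx$taxon_B, expansion_depth = 1)
  sw <- transfer(fx$annotated_B, fx$annotated_A, fx$groups,
                 fx$taxon_B, fx$taxon_A, expansion_depth = 1)
  expect_equal(sw$pairs$gene_A, r$pairs$gene_B[order(r$pairs$gene_B,
                                                     r$pairs$gene_A)])
  expect_equal(sw$new_A, r$new_B)
  expect_equal(sw$new_B, r$new_A)
  expect_equal(sw$excluded_groups, r$excluded_groups)
  expect_equal(sw$expansion_new, r$expansion_new)
})

test_that("empty annotation sets give an inert result", {
  fx <- toy_transfer_fixture()
  r <- transfer(character(), character(), fx$groups, "hsa", "ath")
  expect_equal(nrow(r$pairs), 0)
  expect_length(r$new_A, 0)
  expect_length(r$new_B, 0)
  expect_length(r$excluded_groups, 0)
})

test_that("transfer equals the exhaustive triple-scan oracle on seeded tables", {
  for (s in 1:5) {
    set.seed(900 + s)
    g <- random_groups(30, 50)
    annA <- unique(g$gene[g$taxon == "hsa"])
    annB <- unique(g$gene[g$taxon == "ath"])
    annA <- sample(annA, ceiling(length(annA) / 2))
    annB <- sample(annB, ceiling(length(annB) / 2))
    got <- transfer(annA, annB, g, "hsa", "ath", expansion_depth = 0)
    want <- transfer_oracle(annA, annB, g, "hsa", "ath")
    expect_equal(as.matrix(got$pairs), unname(want$pairs),
                 ignore_attr = TRUE)
    expect_equal(got$new_A, want$new_A)
    expect_equal(got$new_B, want$new_B)
    expect_equal(got$excluded_groups, want$excluded)
  }
})

test_that("annotating an inferred gene moves it out of the new set", {
  fx <- toy_transfer_fixture()
  r <- transfer(fx$annotated_A, fx$annotated_B, fx$groups,
                fx$taxon_A, fx$taxon_B)
  expect_true("i" %in% r$new_B)
  r2 <- transfer(fx$annotated_A, c(fx$annotated_B, "i"), fx$groups,
                 fx$taxon_A, fx$taxon_B)
  expect_false("i" %in% r2$new_B)
  # pairs can only grow: i is now pairable with a through group A
  expect_true(all(paste(r$pairs$gene_A, r$pairs$gene_B) %in%
                    paste(r2$pairs$gene_A, r2$pairs$gene_B)))
  expect_true(any(r2$pairs$gene_A == "a" & r2$pairs$gene_B == "i"))
})

test_that("depth 0 results are contained in depth 1 results", {
  set.seed(321)
  g <- random_groups(40, 60)
  annA <- sample(unique(g$gene[g$taxon == "hsa"]), 10)
  annB <- sample(unique(g$gene[g$taxon == "ath"]), 10)
  r0 <- transfer(annA, annB, g, "hsa", "ath", expansion_depth = 0)
  r1 <- transfer(annA, annB, g, "hsa", "ath", expansion_depth = 1)
  expect_equal(r0$pairs, r1$pairs)
  expect_equal(r0$new_A, r1$new_A)
  expect_true(nrow(r1$expansion_new) >= nrow(r0$expansion_new))
})

test_that("counterpart lookup resolves proteins through shared groups", {
  groups <- load_orthogroups(ext_fixture("counterpart_groups.txt"))
  map_ath <- read.delim(ext_fixture("idmap_ath.tsv"), comment.char = "#")
  map_hsa <- read.delim(ext_fixture("idmap_hsa.tsv"), comment.char = "#")
  res <- find_counterpart_orthologs(c("RAD54", "MC7", "NOSUCH"),
                                    groups, map_ath, map_hsa, "ath", "hsa")
  rad54 <- res[res$query_gene == "RAD54", ]
  expect_equal(rad54$group_id, "OG5_127098")
  expect_equal(rad54$target_genes, "RAD54B;RAD54L")
  expect_equal(rad54$status, "ok")

  mc7 <- res[res$query_gene == "MC7", ]
  expect_equal(mc7$group_id, "none")
  expect_equal(mc7$target_genes, "")
  expect_equal(mc7$status, "no_group")

  expect_equal(res$status[res$query_gene == "NOSUCH"], "unresolved")
})

test_that("gene-level lookup collapses protein isoforms", {
  groups <- load_orthogroups(ext_fixture("counterpart_groups.txt"))
  map_ath <- read.delim(ext_fixture("idmap_ath.tsv"), comment.char = "#")
  map_hsa <- read.delim(ext_fixture("idmap_hsa.tsv"), comment.char = "#")
  msh5 <- find_counterpart_orthologs("MSH5", groups, map_ath, map_hsa,
                                     "ath", "hsa")
  # seven target isoforms, one target gene
  expect_equal(length(strsplit(msh5$target_proteins, ";")[[1]]), 7)
  expect_equal(msh5$target_genes, "MSH5")
})

test_that("summaries reproduce percentages and validate their inputs", {
  fx <- toy_transfer_fixture()
  r <- transfer(fx$annotated_A, fx$annotated_B, fx$groups,
                fx$taxon_A, fx$taxon_B, mechanism = "toy")
  sizes <- data.frame(mechanism = "toy", n_A = 4, n_B = 2)
  s <- summarize_transfers(list(r), sizes)
  # a, b, d pair; e does not; both plant genes pair
  expect_equal(s$n_A_with_orth, 3)
  expect_equal(s$pct_A, 75.0)
  expect_equal(s$n_B_with_orth, 2)
  expect_equal(s$pct_B, 100.0)
  expect_equal(s$n_new_A, 1)
  expect_equal(s$n_new_B, 1)

  # the group rule can only credit more genes than the pair rule
  s_g <- summarize_transfers(list(r), sizes, orth_count_rule = "group")
  expect_true(s_g$n_A_with_orth >= s$n_A_with_orth)

  bad <- data.frame(mechanism = "toy", n_A = 2, n_B = 2)
  expect_error(summarize_transfers(list(r), bad), "inconsistent")
})

test_that("percentage arithmetic is half-up at one decimal", {
  expect_equal(orth_percentage(259, 507), 51.1)
  expect_equal(orth_percentage(9, 73), 12.3)
  expect_equal(orth_percentage(5, 5), 100.0)
  expect_equal(orth_percentage(0, 0), 0)
  expect_equal(orth_percentage(1, 16), 6.3)   # 6.25 rounds up
  expect_error(orth_percentage(5, 4), "exceeds")
})
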