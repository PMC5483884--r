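#' @title Seeded synthetic corpora with planted ground truth
#' @description Generators that emulate the structure the analysis assumes
#'   (a rooted term DAG, per-species annotation sets linked by orthologue
#'   maps, orthogroup tables with planted unannotated genes, interaction
#'   graphs with planted cliques), each a pure function of its seed, plus
#'   the packaged six-group orthogroup toy.
#' @name synthetic
NULL

#' Generate a rooted synthetic term DAG
#'
#' Builds a complete tree of the given depth and branching factor (root at
#' level 0), then adds sparse extra is_a edges from deeper to strictly
#' shallower levels so the result is a genuine DAG rather than a tree. Every
#' non-root term is reachable from the root; the construction is
#' deterministic for a fixed seed.
#'
#' @param depth tree depth (>= 1).
#' @param branching children per internal node (>= 1).
#' @param seed integer seed.
#' @param extra_edge_p probability of one extra cross edge per non-root term.
#' @return a \code{term_dag}; the root is the first term.
#' @export
gen_go_dag <- function(depth, branching, seed = 1, extra_edge_p = 0.1) {
  stopifnot(depth >= 1, branching >= 1)
  with_seed(derive_seed(seed, 1L), {
    n_per_level <- branching^(0:depth)
    n <- sum(n_per_level)
    ids <- sprintf("GO:%07d", seq_len(n))
    level <- rep(0:depth, n_per_level)
    terms <- data.frame(term_id = ids,
                        name = sprintf("synthetic term %d", seq_len(n)),
                        obsolete = FALSE, stringsAsFactors = FALSE)
    child <- character(); parent <- character()
    for (i in which(level > 0)) {
      l <- level[i]
      pos <- i - sum(n_per_level[seq_len(l)])           # 1-based within level l
      p_idx <- sum(n_per_level[seq_len(l - 1)]) + ceiling(pos / branching)
      child <- c(child, ids[i]); parent <- c(parent, ids[p_idx])
    }
    # sparse extra edges to strictly shallower, non-parent terms
    for (i in which(level >= 2)) {
      if (stats::runif(1) < extra_edge_p) {
        cand <- which(level < level[i])
        p2 <- ids[sample(cand, 1)]
        if (!any(child == ids[i] & parent == p2)) {
          child <- c(child, ids[i]); parent <- c(parent, p2)
        }
      }
    }
    edges <- data.frame(child = child, parent = parent, relation = "is_a",
                        stringsAsFactors = FALSE)
    dag <- new_term_dag(terms, edges)
    check_acyclic(dag)
    dag
  })
}

#' Default corpus specification
#'
#' The study conditions for the radiation-biomarker screen: 39 plant species
#' (the reference included) annotated against the seven radiation-quality
#' terms, a reference pool of 410 genes, and realistic noise levels (not all
#' species annotate every gene; some source genes lack a reference
#' counterpart; some genes respond to more than one radiation quality).
#'
#' @param seed integer corpus seed.
#' @return a list understood by \code{\link{gen_projection_corpus}}.
#' @export
default_corpus_spec <- function(seed = 1) {
  list(
    seed = seed,
    n_species = 39,
    reference = "Athaliana",
    categories = c("X-ray", "gamma-ray", "UV-A", "UV-B", "UV-C",
                   "Ionizing Radiation", "UV"),
    term_ids = c("GO:0010165", "GO:0010332", "GO:0070141", "GO:0010224",
                 "GO:0010225", "GO:0010212", "GO:0009411"),
    gene_pool_size = 410,
    annotation_rate = 0.5,
    cross_category_overlap = 0.1,
    orthology_retention = 0.95
  )
}

#' Generate a projection corpus with planted exclusivity truth
#'
#' Plants each reference gene in one home category (plus, with probability
#' \code{cross_category_overlap}, one extra category), then samples which
#' species annotate which planted gene at \code{annotation_rate}. Non-
#' reference species carry their own source-gene ids, linked to the
#' reference gene through the orthologue map with probability
#' \code{orthology_retention}. Every (species, term) pair is guaranteed at
#' least one annotation, so a corpus with \code{n_species} species and k
#' terms always yields exactly \code{n_species * k} annotation sets. With
#' overlap 0 and retention 1 the downstream exclusivity output equals the
#' planted truth exactly.
#'
#' @param spec list as returned by \code{\link{default_corpus_spec}};
#'   component defaults are filled in from it.
#' @return list with \code{annotations} (species, term_id, gene_id),
#'   \code{maps} (species, source_gene, reference_gene), \code{selection}
#'   (a \code{term_selection} over the corpus terms), and \code{truth}
#'   (list: \code{planted_exclusive} named list over categories,
#'   \code{gene_categories} named list gene -> planted categories).
#' @export
gen_projection_corpus <- function(spec = default_corpus_spec()) {
  defaults <- default_corpus_spec()
  for (nm in names(defaults)) if (is.null(spec[[nm]])) spec[[nm]] <- defaults[[nm]]
  stopifnot(spec$n_species >= 1,
            spec$annotation_rate > 0, spec$annotation_rate <= 1,
            spec$cross_category_overlap >= 0, spec$cross_category_overlap <= 1,
            spec$orthology_retention > 0, spec$orthology_retention <= 1,
            length(spec$categories) == length(spec$term_ids))

  with_seed(derive_seed(spec$seed, 2L), {
    cats <- spec$categories
    terms <- stats::setNames(spec$term_ids, cats)
    ref <- spec$reference
    species <- c(ref, sprintf("plant_%02d", seq_len(spec$n_species - 1) + 1))

    n_genes <- spec$gene_pool_size
    ref_genes <- sprintf("AT%dG%05d", 1 + (seq_len(n_genes) - 1) %% 5,
                         10 + 10 * seq_len(n_genes))
    home <- sample(cats, n_genes, replace = TRUE)
    gene_categories <- stats::setNames(as.list(home), ref_genes)
    extra <- stats::runif(n_genes) < spec$cross_category_overlap
    for (i in which(extra)) {
      gene_categories[[i]] <- sort(c(home[i],
                                     sample(setdiff(cats, home[i]), 1)))
    }

    ann_sp <- character(); ann_term <- character(); ann_gene <- character()
    map_sp <- character(); map_src <- character(); map_ref <- character()
    observable <- stats::setNames(logical(n_genes), ref_genes)

    for (s in species) {
      src_of <- stats::setNames(sprintf("%s_g%04d", s, seq_len(n_genes)),
                                ref_genes)
      retained <- stats::setNames(
        stats::runif(n_genes) < spec$orthology_retention, ref_genes)
      for (g in ref_genes) {
        for (cat in gene_categories[[g]]) {
          if (stats::runif(1) < spec$annotation_rate) {
            if (s == ref) {
              ann_sp <- c(ann_sp, s); ann_term <- c(ann_term, terms[[cat]])
              ann_gene <- c(ann_gene, g)
              observable[g] <- TRUE
            } else {
              ann_sp <- c(ann_sp, s); ann_term <- c(ann_term, terms[[cat]])
              ann_gene <- c(ann_gene, src_of[[g]])
              if (retained[[g]]) observable[g] <- TRUE
            }
          }
        }
      }
      if (s != ref) {
        keep <- retained
        map_sp <- c(map_sp, rep(s, sum(keep)))
        map_src <- c(map_src, unname(src_of[keep]))
        map_ref <- c(map_ref, ref_genes[keep])
      }
      # guarantee every (species, term) set is non-empty
      for (cat in cats) {
        present <- any(ann_sp == s & ann_term == terms[[cat]])
        if (!present) {
          pool <- ref_genes[vapply(gene_categories, function(cc) cat %in% cc,
                                   logical(1))]
          if (!length(pool)) { # category with no planted gene: adopt one
            g <- sample(ref_genes, 1)
            gene_categories[[g]] <- sort(c(gene_categories[[g]], cat))
          } else {
            g <- pool[1]
          }
          ann_sp <- c(ann_sp, s); ann_term <- c(ann_term, terms[[cat]])
          if (s == ref) {
            ann_gene <- c(ann_gene, g)
            observable[g] <- TRUE
          } else {
            ann_gene <- c(ann_gene, src_of[[g]])
            if (!retained[[g]]) { # force a retained mapping for the filler
              map_sp <- c(map_sp, s); map_src <- c(map_src, src_of[[g]])
              map_ref <- c(map_ref, g)
              retained[[g]] <- TRUE
            }
            observable[g] <- TRUE
          }
        }
      }
    }

    annotations <- unique(data.frame(species = ann_sp, term_id = ann_term,
                                     gene_id = ann_gene,
                                     stringsAsFactors = FALSE))
    maps <- unique(data.frame(species = map_sp, source_gene = map_src,
                              reference_gene = map_ref,
                              stringsAsFactors = FALSE))

    planted_exclusive <- stats::setNames(
      lapply(cats, function(cat) {
        sort(ref_genes[observable &
                         vapply(gene_categories, function(cc)
                           identical(cc, cat), logical(1))])
      }), cats)

    dag <- radiation_dag_for(cats, terms)
    selection <- select_terms(dag$dag, dag$root,
                              data.frame(term_id = unname(terms),
                                         category = cats,
                                         stringsAsFactors = FALSE))

    list(annotations = annotations, maps = maps, selection = selection,
         truth = list(planted_exclusive = planted_exclusive,
                      gene_categories = gene_categories))
  })
}

# Minimal DAG holding the corpus terms under a synthetic root, so that
# select_terms() validates. Categories whose term id is not one of the
# radiation snapshot terms hang directly off the root.
radiation_dag_for <- function(cats, terms) {
  root <- "GO:0009314"
  ids <- c(root, unname(terms))
  nms <- c("response to radiation", paste("response:", cats))
  extra <- data.frame(child = character(), parent = character(),
                      stringsAsFactors = FALSE)
  # place UV-A/B/C under UV and X-ray/gamma under ionizing radiation when
  # those parents are part of the corpus, mirroring the real hierarchy
  parent_of <- stats::setNames(rep(root, length(terms)), unname(terms))
  if ("GO:0009411" %in% terms) {
    for (t in intersect(c("GO:0070141", "GO:0010224", "GO:0010225"), terms))
      parent_of[[t]] <- "GO:0009411"
  }
  if ("GO:0010212" %in% terms) {
    for (t in intersect(c("GO:0010165", "GO:0010332"), terms))
      parent_of[[t]] <- "GO:0010212"
  }
  edges <- data.frame(child = unname(terms), parent = unname(parent_of),
                      relation = "is_a", stringsAsFactors = FALSE)
  dag <- new_term_dag(
    data.frame(term_id = ids, name = nms, obsolete = FALSE,
               stringsAsFactors = FALSE), edges)
  list(dag = dag, root = root)
}

#' Generate an orthogroup corpus with planted new genes
#'
#' Creates a groups table over two taxa in which a configurable number of
#' unannotated "new" genes are planted inside both-taxa groups that also
#' contain annotated genes; at zero noise the transfer stage recovers
#' exactly the planted set. Additional single-taxon groups with annotated
#' members are generated so the exclusion channel is exercised.
#'
#' @param n_groups total number of groups (>= 2).
#' @param n_genes_per_taxon annotated genes per taxon.
#' @param planted_new number of planted unannotated genes (alternating
#'   taxa); must not exceed the capacity of the both-taxa groups.
#' @param seed integer seed.
#' @param taxon_A,taxon_B taxon labels.
#' @param p_both fraction of groups containing both taxa.
#' @return list with \code{groups} (an \code{orthogroup_table}),
#'   \code{annotated_A}, \code{annotated_B}, and \code{truth}
#'   (data.frame \code{taxon}, \code{gene}, \code{group_id} of planted new
#'   genes).
#' @export
gen_orthogroup_corpus <- function(n_groups = 12, n_genes_per_taxon = 25,
                                  planted_new = 5, seed = 1,
                                  taxon_A = "hsa", taxon_B = "ath",
                                  p_both = 0.6) {
  stopifnot(n_groups >= 2, n_genes_per_taxon >= 1, planted_new >= 0)
  with_seed(derive_seed(seed, 3L), {
    annotated_A <- sprintf("%s_G%03d", taxon_A, seq_len(n_genes_per_taxon))
    annotated_B <- sprintf("%s_G%03d", taxon_B, seq_len(n_genes_per_taxon))
    n_both <- max(1L, round(p_both * n_groups))
    if (planted_new > 0 && n_both < 1)
      stop("infeasible planting: no both-taxa group available")

    gid <- sprintf("SYN_OG%04d", seq_len(n_groups))
    rows <- list()
    # both-taxa groups seeded with 1-2 annotated genes per taxon
    poolA <- sample(annotated_A); poolB <- sample(annotated_B)
    ai <- 1L; bi <- 1L
    take <- function(pool, i, k) {
      idx <- ((i - 1L + seq_len(k) - 1L) %% length(pool)) + 1L
      pool[idx]
    }
    for (j in seq_len(n_both)) {
      ka <- sample(1:2, 1); kb <- sample(1:2, 1)
      ga <- take(poolA, ai, ka); ai <- ai + ka
      gb <- take(poolB, bi, kb); bi <- bi + kb
      rows[[length(rows) + 1L]] <-
        data.frame(group_id = gid[j],
                   taxon = c(rep(taxon_A, ka), rep(taxon_B, kb)),
                   gene = c(ga, gb), stringsAsFactors = FALSE)
    }
    # single-taxon groups with annotated members (exclusion channel)
    for (j in seq(n_both + 1L, n_groups)) {
      tx <- if (j %% 2 == 0) taxon_A else taxon_B
      g <- if (tx == taxon_A) take(poolA, ai, 2L) else take(poolB, bi, 2L)
      if (tx == taxon_A) ai <- ai + 2L else bi <- bi + 2L
      rows[[length(rows) + 1L]] <-
        data.frame(group_id = gid[j], taxon = tx, gene = unique(g),
                   stringsAsFactors = FALSE)
    }
    groups <- do.call(rbind, rows)

    # plant unannotated genes into both-taxa groups
    truth <- data.frame(taxon = character(), gene = character(),
                        group_id = character(), stringsAsFactors = FALSE)
    if (planted_new > 0) {
      host <- sample(gid[seq_len(n_both)], planted_new, replace = TRUE)
      for (i in seq_len(planted_new)) {
        tx <- if (i %% 2 == 1) taxon_B else taxon_A
        gene <- sprintf("%s_NEW%03d", tx, i)
        groups <- rbind(groups,
                        data.frame(group_id = host[i], taxon = tx,
                                   gene = gene, stringsAsFactors = FALSE))
        truth <- rbind(truth,
                       data.frame(taxon = tx, gene = gene,
                                  group_id = host[i],
                                  stringsAsFactors = FALSE))
      }
    }
    groups <- groups[order(match(groups$group_id, gid)), , drop = FALSE]
    groups <- unique(groups)
    rownames(groups) <- NULL
    class(groups) <- c("orthogroup_table", "data.frame")
    list(groups = groups, annotated_A = annotated_A,
         annotated_B = annotated_B, truth = truth)
  })
}

#' Generate an interaction network with planted cliques
#'
#' Planted cliques are fully wired at the maximum confidence score (999);
#' background edges are sampled Bernoulli(\code{background_p}) over all
#' remaining node pairs at a mid confidence score (500).
#'
#' @param n_nodes number of nodes (labelled \code{g001}, ...).
#' @param background_p background edge probability.
#' @param planted_cliques list of character vectors of member nodes (each of
#'   size >= 3, members drawn from the node set).
#' @param seed integer seed.
#' @return a \code{ppi_network}.
#' @export
gen_ppi <- function(n_nodes, background_p = 0.05,
                    planted_cliques = list(), seed = 1) {
  stopifnot(n_nodes >= 1, background_p >= 0, background_p <= 1)
  nodes <- sprintf("g%03d", seq_len(n_nodes))
  for (cl in planted_cliques) {
    if (length(cl) < 3) stop("planted cliques must have size >= 3")
    if (!all(cl %in% nodes)) stop("planted clique members must be nodes")
  }
  with_seed(derive_seed(seed, 4L), {
    ea <- character(); eb <- character(); sc <- numeric()
    for (cl in planted_cliques) {
      pr <- utils::combn(sort(cl), 2)
      ea <- c(ea, pr[1, ]); eb <- c(eb, pr[2, ]); sc <- c(sc, rep(999, ncol(pr)))
    }
    if (background_p > 0 && n_nodes >= 2) {
      pr <- utils::combn(nodes, 2)
      keep <- stats::runif(ncol(pr)) < background_p
      ea <- c(ea, pr[1, keep]); eb <- c(eb, pr[2, keep])
      sc <- c(sc, rep(500, sum(keep)))
    }
    ppi_network(data.frame(node_a = ea, node_b = eb, score = sc,
                           stringsAsFactors = FALSE), nodes = nodes)
  })
}

#' The packaged six-group orthogroup toy
#'
#' Returns the small worked example of the transfer algorithm: six groups
#' (A-F) over a human and a plant taxon, with human genes a, b, d, e and
#' plant genes ii, iii annotated for the mechanism under study. Groups A-C
#' contain both taxa, D-E only plant genes, F only human genes. Running
#' \code{\link{transfer}} at depth 1 pairs (a, ii), infers the plant gene i
#' and the human gene c as new, reaches the plant gene iv through the second
#' hop, and excludes group F (hence the annotated human gene e).
#'
#' @return list with \code{groups}, \code{annotated_A}, \code{annotated_B},
#'   \code{taxon_A}, \code{taxon_B} and \code{expected} (the asserted
#'   relations).
#' @export
toy_transfer_fixture <- function() {
  path <- system.file("extdata", "toy_orthogroups.txt", package = "orthoscreen")
  groups <- load_orthogroups(path)
  list(
    groups = groups,
    annotated_A = c("a", "b", "d", "e"),
    annotated_B = c("ii", "iii"),
    taxon_A = "hsa", taxon_B = "ath",
    expected = list(
      pair = c(gene_A = "a", gene_B = "ii"),
      new_B = "i",
      new_A = "c",
      expansion = data.frame(taxon = "ath", gene = "iv",
                             stringsAsFactors = FALSE),
      excluded = "F"
    )
  )
}
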