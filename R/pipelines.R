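#' @title End-to-end pipeline drivers
#' @description Config-driven orchestration of the two analyses: the
#'   radiation-biomarker screen (ontology -> projection -> exclusivity ->
#'   network -> ranking -> counterpart lookup) and the cross-kingdom repair
#'   comparison (ontology -> per-taxon annotations -> transfer -> summary).
#'   Configs are plain lists or YAML files; all outputs are TSV plus a JSON
#'   run manifest, sorted on documented keys so reruns are byte-identical.
#' @name pipelines
NULL

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("configuration error: no such file: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("configuration error: config must be a list or YAML path")
  config
}

require_fields <- function(config, fields) {
  missing <- fields[!vapply(fields, function(f) !is.null(config[[f]]), logical(1))]
  if (length(missing))
    stop("configuration error: missing field(s): ",
         paste(missing, collapse = ", "))
}

require_paths <- function(config, fields) {
  for (f in fields) {
    if (!file.exists(config[[f]]))
      stop("configuration error: path for '", f, "' not found: ", config[[f]])
  }
}

load_curated <- function(curated) {
  if (is.character(curated) && length(curated) == 1) {
    curated <- read_tsv_strict(curated, c("term_id", "category"))
  }
  curated
}

#' Run the radiation-biomarker screening pipeline
#'
#' Executes the full screen: load the ontology snapshot and validate the
#' curated term selection; load per-species annotations and project them to
#' the reference species through the orthologue maps; partition the
#' projected category sets into Venn cells and keep the quality-exclusive
#' genes; score the interaction network by clique participation and
#' shortlist hub candidates per category; rank the shortlist by species
#' multiplicity; optionally look up counterpart orthologues in a second
#' taxon. Per-stage tables and a JSON manifest are written to the output
#' directory.
#'
#' @param config list or YAML path with fields \code{ontology},
#'   \code{root_term}, \code{curated} (TSV path or data.frame),
#'   \code{annotations}, \code{ortholog_maps}, \code{reference},
#'   \code{ppi_edges}, \code{out_dir}; optional \code{annotation_dialect}
#'   (default \code{"tsv"}), \code{min_score} (400),
#'   \code{min_clique_size} (3), \code{top_n} (10), \code{leaf_categories}
#'   (default: all curated categories) and a \code{counterpart} block
#'   (\code{orthogroups}, \code{id_map_query}, \code{id_map_target},
#'   \code{query_taxon}, \code{target_taxon}).
#' @return invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_biodosimeter <- function(config) {
  config <- read_config(config)
  require_fields(config, c("ontology", "root_term", "curated", "annotations",
                           "ortholog_maps", "reference", "ppi_edges",
                           "out_dir"))
  require_paths(config, c("ontology", "annotations", "ortholog_maps",
                          "ppi_edges"))
  min_score <- config$min_score %||% 400
  min_clique_size <- config$min_clique_size %||% 3
  top_n <- config$top_n %||% 10
  dialect <- config$annotation_dialect %||% "tsv"

  message("[ontology] loading ", config$ontology)
  dag <- load_obo(config$ontology)
  selection <- select_terms(dag, config$root_term,
                            load_curated(config$curated))

  message("[projection] loading annotations and orthologue maps")
  annotations <- load_annotations(config$annotations, dialect = dialect)
  maps <- load_ortholog_maps(config$ortholog_maps)
  projected <- project_to_reference(annotations, maps, config$reference,
                                    selection)
  message("[projection] ", attr(projected, "dropped"),
          " annotation triple(s) dropped for lack of a reference counterpart")
  mult <- multiplicity(projected)

  message("[setops] partitioning ", length(unique(projected$category)),
          " category sets")
  family <- split(projected$reference_gene, projected$category)
  family <- lapply(family, unique)
  part <- venn_partition(family)
  leaf <- config$leaf_categories %||% selection$selection$category
  leaf <- intersect(leaf, part$categories)
  excl <- exclusive_genes(part, leaf)

  message("[network] loading edges at min_score ", min_score)
  net <- load_ppi_edges(config$ppi_edges, min_score = min_score)
  scores <- clique_node_scores(net, min_size = min_clique_size)
  hubs <- select_hub_candidates(scores, excl$exclusive, top_n = top_n)
  shortlist <- unique(unlist(hubs, use.names = FALSE))
  node_scores <- stats::setNames(scores$clique_score, scores$node)
  ranking <- if (length(shortlist)) {
    rank_candidates(projected, node_scores, shortlist)
  } else {
    data.frame(category = character(), reference_gene = character(),
               multiplicity = integer(), node_score = numeric())
  }

  counterparts <- NULL
  if (!is.null(config$counterpart)) {
    cp <- config$counterpart
    require_fields(cp, c("orthogroups", "id_map_query", "id_map_target",
                         "query_taxon", "target_taxon"))
    require_paths(cp, c("orthogroups", "id_map_query", "id_map_target"))
    message("[transfer] counterpart lookup for ", length(shortlist), " genes")
    counterparts <- find_counterpart_orthologs(
      shortlist, load_orthogroups(cp$orthogroups),
      read_tsv_strict(cp$id_map_query, c("gene_id", "protein_id")),
      read_tsv_strict(cp$id_map_target, c("gene_id", "protein_id")),
      cp$query_taxon, cp$target_taxon)
  }

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_tsv(as.data.frame(projected), file.path(out, "projected.tsv"))
  write_tsv(mult, file.path(out, "multiplicity.tsv"))
  cells <- do.call(rbind, lapply(names(part$cells), function(lbl) {
    if (!length(part$cells[[lbl]])) return(NULL)
    data.frame(cell = lbl, gene = part$cells[[lbl]], stringsAsFactors = FALSE)
  }))
  if (is.null(cells)) cells <- data.frame(cell = character(), gene = character())
  write_tsv(cells, file.path(out, "venn_cells.tsv"))
  excl_df <- do.call(rbind, lapply(names(excl$exclusive), function(cat) {
    if (!length(excl$exclusive[[cat]])) return(NULL)
    data.frame(category = cat, gene = excl$exclusive[[cat]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(excl_df))
    excl_df <- data.frame(category = character(), gene = character())
  write_tsv(excl_df, file.path(out, "exclusive.tsv"))
  write_tsv(scores, file.path(out, "node_scores.tsv"))
  write_tsv(ranking, file.path(out, "candidates.tsv"))
  if (!is.null(counterparts))
    write_tsv(counterparts, file.path(out, "counterparts.tsv"))

  manifest <- list(
    pipeline = "biodosimeter",
    inputs = config[c("ontology", "annotations", "ortholog_maps",
                      "ppi_edges")],
    parameters = list(root_term = selection$root_id, reference = config$reference,
                      min_score = min_score, min_clique_size = min_clique_size,
                      top_n = top_n, leaf_categories = leaf),
    counts = list(
      n_terms_selected = nrow(selection$selection),
      n_annotation_sets = n_annotation_sets(annotations),
      n_projected_genes = length(unique(projected$reference_gene)),
      n_dropped_unmapped = attr(projected, "dropped"),
      venn_cell_sizes = as.list(stats::setNames(lengths(part$cells),
                                                names(part$cells))),
      n_exclusive = as.list(lengths(excl$exclusive)),
      n_parent_only = length(excl$parent_only),
      n_network_nodes = length(net$nodes),
      n_network_edges = nrow(net$edges),
      n_candidates = nrow(ranking)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(selection = selection, annotations = annotations,
                 projected = projected, multiplicity = mult,
                 partition = part, exclusive = excl, network = net,
                 node_scores = scores, hubs = hubs, ranking = ranking,
                 counterparts = counterparts, manifest = manifest))
}

#' Run the cross-kingdom repair comparison pipeline
#'
#' For each mechanism of the curated selection, builds the annotated gene
#' set of each taxon from its annotation table, runs the orthogroup transfer
#' and writes orthologue pairs, inferred new genes and the per-mechanism
#' count/percentage summary.
#'
#' @param config list or YAML path with fields \code{ontology},
#'   \code{root_term}, \code{curated}, \code{annotations_A},
#'   \code{annotations_B} (TSVs with columns \code{term_id},
#'   \code{gene_id}), \code{taxon_A}, \code{taxon_B}, \code{orthogroups},
#'   \code{out_dir}; optional \code{expansion_depth} (0) and
#'   \code{orth_count_rule} (\code{"pair"}).
#' @return invisibly, a list with per-mechanism \code{transfer_result}s, the
#'   summary table and the manifest.
#' @export
run_repair_comparison <- function(config) {
  config <- read_config(config)
  require_fields(config, c("ontology", "root_term", "curated",
                           "annotations_A", "annotations_B",
                           "taxon_A", "taxon_B", "orthogroups", "out_dir"))
  require_paths(config, c("ontology", "annotations_A", "annotations_B",
                          "orthogroups"))
  depth <- config$expansion_depth %||% 0
  rule <- config$orth_count_rule %||% "pair"

  message("[ontology] loading ", config$ontology)
  dag <- load_obo(config$ontology)
  selection <- select_terms(dag, config$root_term,
                            load_curated(config$curated))

  ann_A <- read_tsv_strict(config$annotations_A, c("term_id", "gene_id"))
  ann_B <- read_tsv_strict(config$annotations_B, c("term_id", "gene_id"))
  ann_A$term_id <- normalize_term_id(ann_A$term_id)
  ann_B$term_id <- normalize_term_id(ann_B$term_id)
  groups <- load_orthogroups(config$orthogroups)

  mechs <- selection$selection$category
  results <- list(); sizes <- list()
  for (i in seq_along(mechs)) {
    term <- selection$selection$term_id[i]
    genes_A <- unique(trim(ann_A$gene_id[ann_A$term_id == term]))
    genes_B <- unique(trim(ann_B$gene_id[ann_B$term_id == term]))
    message("[transfer] ", mechs[i], ": ", length(genes_A), " ",
            config$taxon_A, " genes vs ", length(genes_B), " ",
            config$taxon_B, " genes")
    results[[mechs[i]]] <- transfer(genes_A, genes_B, groups,
                                    config$taxon_A, config$taxon_B,
                                    expansion_depth = depth,
                                    mechanism = mechs[i])
    sizes[[mechs[i]]] <- data.frame(mechanism = mechs[i],
                                    n_A = length(genes_A),
                                    n_B = length(genes_B),
                                    stringsAsFactors = FALSE)
  }
  summary_df <- summarize_transfers(results, do.call(rbind, sizes),
                                    orth_count_rule = rule)

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  pairs_df <- do.call(rbind, lapply(mechs, function(m) {
    p <- results[[m]]$pairs
    if (!nrow(p)) return(NULL)
    cbind(data.frame(mechanism = m, stringsAsFactors = FALSE), p)
  }))
  if (is.null(pairs_df))
    pairs_df <- data.frame(mechanism = character(), gene_A = character(),
                           gene_B = character())
  write_tsv(pairs_df, file.path(out, "pairs.tsv"))

  new_df <- do.call(rbind, lapply(mechs, function(m) {
    r <- results[[m]]
    rbind(
      if (length(r$new_A))
        data.frame(mechanism = m, taxon = r$taxon_A, gene = r$new_A,
                   hop = 0L, stringsAsFactors = FALSE),
      if (length(r$new_B))
        data.frame(mechanism = m, taxon = r$taxon_B, gene = r$new_B,
                   hop = 0L, stringsAsFactors = FALSE),
      if (nrow(r$expansion_new))
        data.frame(mechanism = m, taxon = r$expansion_new$taxon,
                   gene = r$expansion_new$gene, hop = 1L,
                   stringsAsFactors = FALSE))
  }))
  if (is.null(new_df))
    new_df <- data.frame(mechanism = character(), taxon = character(),
                         gene = character(), hop = integer())
  write_tsv(new_df, file.path(out, "new_genes.tsv"))
  write_tsv(summary_df, file.path(out, "summary.tsv"))

  manifest <- list(
    pipeline = "repair_comparison",
    inputs = config[c("ontology", "annotations_A", "annotations_B",
                      "orthogroups")],
    parameters = list(root_term = selection$root_id,
                      taxon_A = config$taxon_A, taxon_B = config$taxon_B,
                      expansion_depth = depth, orth_count_rule = rule),
    counts = list(n_mechanisms = length(mechs),
                  n_pairs = nrow(pairs_df),
                  n_new_genes = nrow(new_df),
                  n_groups = length(unique(groups$group_id))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(selection = selection, results = results,
                 summary = summary_df, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
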