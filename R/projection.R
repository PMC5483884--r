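#' @title Orthologue projection of annotation sets onto a reference species
#' @description Read per-species GO annotation tables, project them onto a
#'   reference species through pairwise orthologue maps, count per-gene
#'   species multiplicity and rank shortlisted candidates.
#' @name projection
NULL

#' Load per-species annotation sets
#'
#' Two dialects are supported. \code{"tsv"} expects a tab-separated file with
#' header columns \code{species}, \code{term_id}, \code{gene_id}. \code{"gaf"}
#' reads GAF 2.x: comment lines start with \code{!}; the DB object id
#' (column 2), qualifier (column 4), GO id (column 5) and taxon (column 13)
#' are used, the taxon serving as the species label. Rows whose qualifier
#' contains \code{NOT} are dropped, as negated annotations must not seed a
#' projection.
#'
#' @param path input file.
#' @param dialect \code{"tsv"} or \code{"gaf"}.
#' @return data.frame with columns \code{species}, \code{term_id},
#'   \code{gene_id}; one row per annotation. Each distinct
#'   (species, term) pair constitutes one annotation set.
#' @export
load_annotations <- function(path, dialect = c("tsv", "gaf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  if (dialect == "tsv") {
    df <- read_tsv_strict(path, c("species", "term_id", "gene_id"))
    bad <- which(!nzchar(trim(df$species)) | !nzchar(trim(df$gene_id)))
    if (length(bad))
      stop("malformed annotation row at data line ", bad[1], " of ", path)
    out <- data.frame(species = trim(df$species),
                      term_id = normalize_term_id(df$term_id),
                      gene_id = trim(df$gene_id),
                      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^!", lines) & nzchar(lines)
    lines <- lines[keep]
    lineno <- which(keep)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 13))
      stop("malformed GAF row at line ", lineno[which(nf < 13)[1]],
           " of ", path, " (fewer than 13 columns)")
    gene <- vapply(fields, `[`, "", 2L)
    qualifier <- vapply(fields, `[`, "", 4L)
    term <- vapply(fields, `[`, "", 5L)
    taxon <- vapply(fields, `[`, "", 13L)
    not <- vapply(strsplit(qualifier, "|", fixed = TRUE),
                  function(q) any(trim(q) == "NOT"), logical(1))
    out <- data.frame(species = sub("^taxon:", "", taxon)[!not],
                      term_id = normalize_term_id(term[!not]),
                      gene_id = trim(gene[!not]),
                      stringsAsFactors = FALSE)
  }
  unique(out)
}

#' Number of per-(species, term) annotation sets
#'
#' @param annotations output of \code{\link{load_annotations}} or a
#'   compatible data.frame.
#' @return integer count of distinct (species, term_id) pairs.
#' @export
n_annotation_sets <- function(annotations) {
  nrow(unique(annotations[, c("species", "term_id")]))
}

#' Load pairwise orthologue maps
#'
#' @param path TSV with header columns \code{species}, \code{source_gene},
#'   \code{reference_gene}.
#' @return data.frame of unique orthologue pairs.
#' @export
load_ortholog_maps <- function(path) {
  df <- read_tsv_strict(path, c("species", "source_gene", "reference_gene"))
  unique(data.frame(species = trim(df$species),
                    source_gene = trim(df$source_gene),
                    reference_gene = trim(df$reference_gene),
                    stringsAsFactors = FALSE))
}

#' Project annotation sets onto the reference species
#'
#' For every annotation (species, term, gene) whose term belongs to the
#' selection, the gene is mapped to its reference-species counterpart(s)
#' through the orthologue map of that species; the reference species itself
#' contributes through the implied identity map. Orthology may be
#' many-to-many: every mapped reference gene receives a provenance record.
#' Source genes with no reference counterpart are dropped and tallied in the
#' \code{dropped} attribute.
#'
#' @param annotations data.frame (\code{species}, \code{term_id},
#'   \code{gene_id}).
#' @param maps data.frame (\code{species}, \code{source_gene},
#'   \code{reference_gene}); see \code{\link{load_ortholog_maps}}.
#' @param reference name of the reference species.
#' @param selection a \code{term_selection}; annotations to terms outside the
#'   selection are ignored.
#' @return object of class \code{projected_annotation}: data.frame with one
#'   provenance row per (category, reference_gene, species, source_gene),
#'   carrying attribute \code{dropped} (count of annotation triples whose
#'   source gene had no reference counterpart).
#' @export
project_to_reference <- function(annotations, maps, reference, selection) {
  stopifnot(inherits(selection, "term_selection"))
  ann <- annotations[annotations$term_id %in% selection$selection$term_id, ,
                     drop = FALSE]
  ann$category <- selection$selection$category[
    match(ann$term_id, selection$selection$term_id)]

  unmapped_species <- setdiff(unique(ann$species),
                              c(reference, unique(maps$species)))
  if (length(unmapped_species))
    stop("species with annotations but no orthologue map: ",
         paste(unmapped_species, collapse = ", "))

  ref_rows <- ann[ann$species == reference, , drop = FALSE]
  oth_rows <- ann[ann$species != reference, , drop = FALSE]

  proj_ref <- data.frame(category = ref_rows$category,
                         reference_gene = ref_rows$gene_id,
                         species = ref_rows$species,
                         source_gene = ref_rows$gene_id,
                         stringsAsFactors = FALSE)

  merged <- merge(oth_rows, maps,
                  by.x = c("species", "gene_id"),
                  by.y = c("species", "source_gene"))
  # dropped: annotation triples whose (species, gene) pair has no map entry
  key_ann <- unique(oth_rows[, c("species", "gene_id", "term_id")])
  key_hit <- unique(merged[, c("species", "gene_id", "term_id")])
  dropped <- nrow(key_ann) - nrow(key_hit)

  proj_oth <- data.frame(category = merged$category,
                         reference_gene = merged$reference_gene,
                         species = merged$species,
                         source_gene = merged$gene_id,
                         stringsAsFactors = FALSE)

  out <- unique(rbind(proj_ref, proj_oth))
  out <- out[order(out$category, out$reference_gene,
                   out$species, out$source_gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, dropped = dropped,
            class = c("projected_annotation", "data.frame"))
}

#' Species multiplicity of projected genes
#'
#' Multiplicity counts distinct contributing species, not orthologue genes:
#' a species with several source genes mapping to the same reference gene
#' counts once.
#'
#' @param projected a \code{projected_annotation}.
#' @return data.frame (\code{category}, \code{reference_gene},
#'   \code{multiplicity}), sorted by category then gene.
#' @export
multiplicity <- function(projected) {
  if (!nrow(projected)) {
    return(data.frame(category = character(), reference_gene = character(),
                      multiplicity = integer(), stringsAsFactors = FALSE))
  }
  sp <- unique(projected[, c("category", "reference_gene", "species")])
  agg <- stats::aggregate(species ~ category + reference_gene, data = sp,
                          FUN = length)
  names(agg)[names(agg) == "species"] <- "multiplicity"
  agg <- agg[order(agg$category, agg$reference_gene), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Rank shortlisted candidate genes
#'
#' Restricts the multiplicity table to a shortlist (typically the dense-clique
#' nodes of the interaction network) and orders rows by multiplicity
#' (descending), then node score (descending), then gene id (ascending).
#' Shortlist genes absent from the projection are kept, with a warning, as
#' multiplicity-0 rows at the bottom.
#'
#' @param projected a \code{projected_annotation}.
#' @param node_scores named numeric vector of per-gene network scores; genes
#'   without a score get 0.
#' @param shortlist character vector of reference gene ids.
#' @return data.frame (\code{category}, \code{reference_gene},
#'   \code{multiplicity}, \code{node_score}) in ranking order.
#' @export
rank_candidates <- function(projected, node_scores = numeric(), shortlist) {
  mult <- multiplicity(projected)
  rows <- mult[mult$reference_gene %in% shortlist, , drop = FALSE]
  absent <- setdiff(shortlist, mult$reference_gene)
  if (length(absent)) {
    warning("shortlist gene(s) absent from projection: ",
            paste(absent, collapse = ", "))
    rows <- rbind(rows, data.frame(category = NA_character_,
                                   reference_gene = absent,
                                   multiplicity = 0L,
                                   stringsAsFactors = FALSE))
  }
  score <- unname(node_scores[rows$reference_gene])
  score[is.na(score)] <- 0
  rows$node_score <- score
  ord <- order(-rows$multiplicity, -rows$node_score, rows$reference_gene)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
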