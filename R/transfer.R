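#' @title Orthogroup-based annotation transfer between two taxa
#' @description Classify orthogroups by taxon composition, pair annotated
#'   orthologues between two taxa, infer not-yet-annotated "new" genes from
#'   shared orthogroup membership, and summarize per-mechanism counts and
#'   orthologue-coverage percentages.
#' @name transfer-module
NULL

#' Load an orthogroup membership file
#'
#' Parses the OrthoMCL "groups" text format: one group per line,
#' \code{GROUP_ID: taxon|gene taxon|gene ...}. Lines starting with \code{#}
#' and blank lines are skipped. Taxa beyond the pair under study are legal
#' members and retained.
#'
#' @param path groups file.
#' @return object of class \code{orthogroup_table}: data.frame with columns
#'   \code{group_id}, \code{taxon}, \code{gene}; one row per member.
#' @export
load_orthogroups <- function(path) {
  if (!file.exists(path)) stop("cannot read orthogroup file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trim(lines)) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  lineno <- which(keep)

  gid <- character(); taxa <- character(); genes <- character()
  seen_ids <- character()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    colon <- regexpr(":", ln, fixed = TRUE)
    if (colon < 1)
      stop("malformed orthogroup line ", lineno[i], " of ", path,
           ": missing ':'")
    id <- trim(substr(ln, 1, colon - 1))
    if (!nzchar(id))
      stop("malformed orthogroup line ", lineno[i], " of ", path,
           ": empty group id")
    if (id %in% seen_ids)
      stop("duplicate group id '", id, "' at line ", lineno[i], " of ", path)
    seen_ids <- c(seen_ids, id)
    members <- strsplit(trim(substr(ln, colon + 1, nchar(ln))), "\\s+")[[1]]
    members <- members[nzchar(members)]
    if (!length(members))
      stop("malformed orthogroup line ", lineno[i], " of ", path,
           ": group has no members")
    parts <- strsplit(members, "|", fixed = TRUE)
    ok <- lengths(parts) == 2L
    if (any(!ok))
      stop("malformed member '", members[which(!ok)[1]], "' at line ",
           lineno[i], " of ", path, " (expected taxon|gene)")
    gid <- c(gid, rep(id, length(members)))
    taxa <- c(taxa, vapply(parts, `[`, "", 1L))
    genes <- c(genes, vapply(parts, `[`, "", 2L))
  }
  out <- unique(data.frame(group_id = gid, taxon = taxa, gene = genes,
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("orthogroup_table", "data.frame")
  out
}

#' Write an orthogroup table in groups format
#'
#' Inverse of \code{\link{load_orthogroups}}; members are written in table
#' order so a generated table round-trips byte-identically.
#'
#' @param groups an \code{orthogroup_table} (or compatible data.frame).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_orthogroups <- function(groups, path) {
  ids <- unique(groups$group_id)
  lines <- vapply(ids, function(id) {
    m <- groups[groups$group_id == id, , drop = FALSE]
    paste0(id, ": ", paste(paste0(m$taxon, "|", m$gene), collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Classify orthogroups by taxon composition
#'
#' @param groups an \code{orthogroup_table}.
#' @param taxon_A,taxon_B the two distinct taxa of interest.
#' @return named character vector mapping group_id to one of \code{"both"},
#'   \code{"A_only"}, \code{"B_only"}, \code{"neither"}.
#' @export
classify_groups <- function(groups, taxon_A, taxon_B) {
  if (identical(taxon_A, taxon_B)) stop("taxa must be distinct")
  ids <- unique(groups$group_id)
  has_A <- tapply(groups$taxon == taxon_A, groups$group_id, any)
  has_B <- tapply(groups$taxon == taxon_B, groups$group_id, any)
  cls <- ifelse(has_A[ids] & has_B[ids], "both",
         ifelse(has_A[ids], "A_only",
         ifelse(has_B[ids], "B_only", "neither")))
  stats::setNames(as.character(cls), ids)
}

#' Transfer annotations between two taxa through shared orthogroups
#'
#' The scan starts from the annotated genes of either taxon and visits every
#' orthogroup containing at least one of them. In a visited group containing
#' members of both taxa: annotated members of taxon A and annotated members
#' of taxon B are paired as orthologues, and unannotated members of either
#' taxon become candidate "new" genes for the mechanism under study. A
#' visited group whose members of interest cover only one of the two taxa is
#' recorded as excluded and yields no pairs. With \code{expansion_depth = 1},
#' a single second hop is taken: every annotated gene's groups (including
#' single-taxon groups) are scanned once and their unannotated same-taxon
#' members are reported as \code{expansion_new}, excluding genes already
#' captured as new in the first pass. Depth is capped at one hop: an
#' unbounded transitive closure over shared orthogroups would flood-fill the
#' orthology graph.
#'
#' @param annotated_A,annotated_B character vectors of annotated gene ids in
#'   taxon A / taxon B namespaces.
#' @param groups an \code{orthogroup_table}.
#' @param taxon_A,taxon_B the two taxa of interest as they appear in
#'   \code{groups}.
#' @param expansion_depth 0 or 1 (see above).
#' @param mechanism optional category tag carried through to summaries.
#' @return object of class \code{transfer_result}: list with
#'   \describe{
#'     \item{pairs}{data.frame (\code{gene_A}, \code{gene_B}) of orthologue
#'       pairs co-occurring in at least one both-taxa group.}
#'     \item{new_A, new_B}{sorted character vectors of inferred new genes.}
#'     \item{expansion_new}{data.frame (\code{taxon}, \code{gene}) of
#'       second-hop candidates.}
#'     \item{excluded_groups}{sorted character vector of group ids.}
#'     \item{with_orth}{per counting rule (\code{pair}, \code{group}), the
#'       annotated genes of each taxon credited with an orthologue.}
#'   }
#' @export
transfer <- function(annotated_A, annotated_B, groups, taxon_A, taxon_B,
                     expansion_depth = 0, mechanism = NA_character_) {
  if (!(length(expansion_depth) == 1 && expansion_depth %in% c(0, 1)))
    stop("expansion_depth must be 0 or 1")
  if (identical(taxon_A, taxon_B)) stop("taxa must be distinct")
  annotated_A <- unique(as.character(annotated_A))
  annotated_B <- unique(as.character(annotated_B))

  cls <- classify_groups(groups, taxon_A, taxon_B)
  is_annot <- (groups$taxon == taxon_A & groups$gene %in% annotated_A) |
              (groups$taxon == taxon_B & groups$gene %in% annotated_B)
  visited <- unique(groups$group_id[is_annot])

  pairs <- data.frame(gene_A = character(), gene_B = character(),
                      stringsAsFactors = FALSE)
  new_A <- character(); new_B <- character()
  excluded <- character()
  with_orth_group_A <- character(); with_orth_group_B <- character()

  for (id in visited) {
    m <- groups[groups$group_id == id, , drop = FALSE]
    if (cls[[id]] == "both") {
      a_ann <- unique(m$gene[m$taxon == taxon_A & m$gene %in% annotated_A])
      b_ann <- unique(m$gene[m$taxon == taxon_B & m$gene %in% annotated_B])
      if (length(a_ann) && length(b_ann))
        pairs <- rbind(pairs, expand.grid(gene_A = a_ann, gene_B = b_ann,
                                          stringsAsFactors = FALSE))
      new_A <- union(new_A,
                     m$gene[m$taxon == taxon_A & !(m$gene %in% annotated_A)])
      new_B <- union(new_B,
                     m$gene[m$taxon == taxon_B & !(m$gene %in% annotated_B)])
      with_orth_group_A <- union(with_orth_group_A, a_ann)
      with_orth_group_B <- union(with_orth_group_B, b_ann)
    } else {
      excluded <- union(excluded, id)
    }
  }
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs$gene_A, pairs$gene_B), , drop = FALSE]
  rownames(pairs) <- NULL

  expansion_new <- data.frame(taxon = character(), gene = character(),
                              stringsAsFactors = FALSE)
  if (expansion_depth == 1) {
    for (id in visited) {
      m <- groups[groups$group_id == id, , drop = FALSE]
      ann_taxa <- unique(m$taxon[(m$taxon == taxon_A & m$gene %in% annotated_A) |
                                 (m$taxon == taxon_B & m$gene %in% annotated_B)])
      for (tx in intersect(ann_taxa, c(taxon_A, taxon_B))) {
        ann_here <- if (tx == taxon_A) annotated_A else annotated_B
        already <- if (tx == taxon_A) new_A else new_B
        cand <- m$gene[m$taxon == tx & !(m$gene %in% ann_here)]
        cand <- setdiff(cand, already)
        if (length(cand))
          expansion_new <- rbind(expansion_new,
                                 data.frame(taxon = tx, gene = cand,
                                            stringsAsFactors = FALSE))
      }
    }
    expansion_new <- unique(expansion_new)
    expansion_new <- expansion_new[order(expansion_new$taxon,
                                         expansion_new$gene), , drop = FALSE]
    rownames(expansion_new) <- NULL
  }

  structure(list(
    mechanism = mechanism,
    taxon_A = taxon_A, taxon_B = taxon_B,
    pairs = pairs,
    new_A = sort(new_A), new_B = sort(new_B),
    expansion_new = expansion_new,
    excluded_groups = sort(excluded),
    with_orth = list(
      pair = list(A = sort(unique(pairs$gene_A)),
                  B = sort(unique(pairs$gene_B))),
      group = list(A = sort(with_orth_group_A),
                   B = sort(with_orth_group_B)))
  ), class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat("transfer_result", if (!is.na(x$mechanism)) paste0("[", x$mechanism, "]"),
      ":", nrow(x$pairs), "pairs;", length(x$new_A), "new", x$taxon_A,
      "genes;", length(x$new_B), "new", x$taxon_B, "genes;",
      nrow(x$expansion_new), "expansion candidates;",
      length(x$excluded_groups), "excluded groups\n")
  invisible(x)
}

#' Look up counterpart orthologues through orthogroups and id maps
#'
#' Resolves each query gene to its protein id(s), finds the orthogroup(s)
#' containing those proteins under the query taxon, collects the group
#' members of the target taxon and maps them back to target gene names.
#' Genes whose protein belongs to no group get group \code{"none"} and empty
#' targets; genes missing from the id map are flagged unresolved rather than
#' raising an error. Multiple values within a cell are joined with
#' \code{";"}.
#'
#' @param query_genes character vector of query gene ids.
#' @param groups an \code{orthogroup_table} keyed by protein ids.
#' @param id_map_query,id_map_target data.frames (\code{gene_id},
#'   \code{protein_id}) for the query and target taxa.
#' @param query_taxon,target_taxon taxon labels as used in \code{groups}.
#' @return data.frame with one row per query gene: \code{query_gene},
#'   \code{query_protein}, \code{group_id}, \code{target_proteins},
#'   \code{target_genes}, \code{status} (\code{ok}, \code{no_group} or
#'   \code{unresolved}).
#' @export
find_counterpart_orthologs <- function(query_genes, groups,
                                       id_map_query, id_map_target,
                                       query_taxon, target_taxon) {
  stopifnot(all(c("gene_id", "protein_id") %in% names(id_map_query)),
            all(c("gene_id", "protein_id") %in% names(id_map_target)))
  rows <- lapply(unique(as.character(query_genes)), function(qg) {
    prots <- id_map_query$protein_id[id_map_query$gene_id == qg]
    if (!length(prots)) {
      return(data.frame(query_gene = qg, query_protein = "",
                        group_id = "", target_proteins = "",
                        target_genes = "", status = "unresolved",
                        stringsAsFactors = FALSE))
    }
    gids <- sort(unique(groups$group_id[groups$taxon == query_taxon &
                                          groups$gene %in% prots]))
    if (!length(gids)) {
      return(data.frame(query_gene = qg,
                        query_protein = paste(sort(prots), collapse = ";"),
                        group_id = "none", target_proteins = "",
                        target_genes = "", status = "no_group",
                        stringsAsFactors = FALSE))
    }
    tp <- sort(unique(groups$gene[groups$group_id %in% gids &
                                    groups$taxon == target_taxon]))
    tg <- sort(unique(id_map_target$gene_id[id_map_target$protein_id %in% tp]))
    data.frame(query_gene = qg,
               query_protein = paste(sort(prots), collapse = ";"),
               group_id = paste(gids, collapse = ";"),
               target_proteins = paste(tp, collapse = ";"),
               target_genes = paste(tg, collapse = ";"),
               status = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-mechanism summary of transfer results
#'
#' Builds the quantitative comparison table: per mechanism, the number of
#' annotated genes in each taxon, how many of them have at least one
#' orthologue in the other taxon, the corresponding percentage (half-up,
#' one decimal), and the counts of inferred new genes. Under the default
#' \code{orth_count_rule = "pair"} a gene counts as having an orthologue if
#' it appears in at least one orthologue pair; under \code{"group"} it
#' suffices to sit in any group containing both taxa.
#'
#' @param results list of \code{transfer_result} objects (named by mechanism
#'   or carrying their own \code{mechanism} field).
#' @param annotated_sizes data.frame (\code{mechanism}, \code{n_A},
#'   \code{n_B}) of annotated-set sizes per mechanism.
#' @param orth_count_rule \code{"pair"} or \code{"group"}.
#' @return data.frame with columns \code{mechanism}, \code{n_A},
#'   \code{n_A_with_orth}, \code{pct_A}, \code{n_B}, \code{n_B_with_orth},
#'   \code{pct_B}, \code{n_new_A}, \code{n_new_B}.
#' @export
summarize_transfers <- function(results, annotated_sizes,
                                orth_count_rule = c("pair", "group")) {
  orth_count_rule <- match.arg(orth_count_rule)
  stopifnot(all(c("mechanism", "n_A", "n_B") %in% names(annotated_sizes)))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    stopifnot(inherits(r, "transfer_result"))
    mech <- if (!is.na(r$mechanism)) r$mechanism else names(results)[i]
    sz <- annotated_sizes[annotated_sizes$mechanism == mech, , drop = FALSE]
    if (nrow(sz) != 1)
      stop("annotated_sizes must have exactly one row for mechanism ", mech)
    wA <- length(r$with_orth[[orth_count_rule]]$A)
    wB <- length(r$with_orth[[orth_count_rule]]$B)
    if (wA > sz$n_A || wB > sz$n_B)
      stop("more genes with orthologues than annotated genes for ", mech,
           ": inconsistent inputs")
    data.frame(mechanism = mech,
               n_A = sz$n_A, n_A_with_orth = wA,
               pct_A = orth_percentage(wA, sz$n_A),
               n_B = sz$n_B, n_B_with_orth = wB,
               pct_B = orth_percentage(wB, sz$n_B),
               n_new_A = length(r$new_A), n_new_B = length(r$new_B),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
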