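#' @title Ontology snapshots as term DAGs
#' @description Load an OBO flat-file snapshot of an ontology into a term
#'   DAG, compute descendant closures over a configurable relation subset,
#'   and validate curated term selections against the hierarchy.
#' @name ontology
NULL

RELATION_LEVELS <- c("is_a", "part_of", "regulates", "other")

# Normalize term identifiers to the canonical "GO:" + 7 digit form where the
# input looks like a GO accession; other identifier schemes pass through
# upper-cased and trimmed.
normalize_term_id <- function(id) {
  id <- toupper(trim(id))
  m <- grepl("^GO:\\d+$", id)
  id[m] <- sprintf("GO:%07d", as.integer(sub("^GO:", "", id[m])))
  id
}

new_term_dag <- function(terms, edges, alt_ids = character()) {
  structure(
    list(terms = terms, edges = edges, alt_ids = alt_ids),
    class = "term_dag"
  )
}

#' Load an OBO ontology snapshot
#'
#' Parses an OBO 1.2/1.4 flat file into a term DAG. Only the stanza fields
#' the downstream analysis needs are read: \code{id}, \code{name},
#' \code{alt_id}, \code{is_obsolete}, \code{is_a} and
#' \code{relationship}. Relationship types other than \code{part_of} and the
#' \code{regulates} family are kept with relation \code{"other"}. The
#' \code{is_a} graph is checked for cycles.
#'
#' @param path path to an OBO file.
#' @return an object of class \code{term_dag} with components
#'   \describe{
#'     \item{terms}{data.frame with columns \code{term_id}, \code{name},
#'       \code{obsolete}.}
#'     \item{edges}{data.frame with columns \code{child}, \code{parent},
#'       \code{relation}; edges point child to parent.}
#'     \item{alt_ids}{named character vector mapping alternative ids to
#'       canonical ids.}
#'   }
#' @export
load_obo <- function(path) {
  if (!file.exists(path)) stop("cannot read OBO file: ", path)
  lines <- readLines(path, warn = FALSE)
  # strip trailing OBO comments ("!"), keeping the payload
  lines <- sub("\\s*!.*$", "", lines)

  stanza_starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]\\s*$", lines)

  ids <- character(); nms <- character(); obs <- logical()
  children <- character(); parents <- character(); relations <- character()
  alt_from <- character(); alt_to <- character()

  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[(s + 1L):end]
    block <- block[nzchar(trim(block))]
    kv <- regmatches(block, regexec("^([A-Za-z_]+):\\s*(.*)$", block))
    keys <- vapply(kv, function(x) if (length(x) == 3) x[2] else NA_character_,
                   character(1))
    vals <- vapply(kv, function(x) if (length(x) == 3) trim(x[3]) else NA_character_,
                   character(1))

    id <- vals[match("id", keys)]
    if (is.na(id)) next
    id <- normalize_term_id(id)
    nm <- vals[match("name", keys)]
    obsolete <- identical(tolower(vals[match("is_obsolete", keys)]), "true")

    ids <- c(ids, id)
    nms <- c(nms, if (is.na(nm)) "" else nm)
    obs <- c(obs, obsolete)

    for (a in vals[keys == "alt_id" & !is.na(keys)]) {
      alt_from <- c(alt_from, normalize_term_id(a))
      alt_to <- c(alt_to, id)
    }
    for (p in vals[keys == "is_a" & !is.na(keys)]) {
      children <- c(children, id)
      parents <- c(parents, normalize_term_id(p))
      relations <- c(relations, "is_a")
    }
    for (r in vals[keys == "relationship" & !is.na(keys)]) {
      parts <- strsplit(trim(r), "\\s+")[[1]]
      if (length(parts) < 2) stop("malformed relationship line in ", path, ": ", r)
      rel <- parts[1]
      rel <- if (rel == "part_of") "part_of"
             else if (grepl("regulates$", rel)) "regulates"
             else "other"
      children <- c(children, id)
      parents <- c(parents, normalize_term_id(parts[2]))
      relations <- c(relations, rel)
    }
  }

  terms <- data.frame(term_id = ids, name = nms, obsolete = obs,
                      stringsAsFactors = FALSE)
  if (anyDuplicated(terms$term_id)) {
    stop("duplicate term id(s) in OBO: ",
         paste(unique(terms$term_id[duplicated(terms$term_id)]), collapse = ", "))
  }
  edges <- data.frame(child = children, parent = parents,
                      relation = relations, stringsAsFactors = FALSE)
  # drop edges whose parent is not defined in this snapshot (dangling refs)
  edges <- edges[edges$parent %in% terms$term_id, , drop = FALSE]
  edges <- unique(edges)
  rownames(edges) <- NULL
  alt_ids <- stats::setNames(alt_to, alt_from)

  dag <- new_term_dag(terms, edges, alt_ids)
  check_acyclic(dag, relations = "is_a")
  dag
}

# Validation error naming a cycle member if the graph over the given
# relations contains a directed cycle.
check_acyclic <- function(dag, relations = "is_a") {
  e <- dag$edges[dag$edges$relation %in% relations, , drop = FALSE]
  if (!nrow(e)) return(invisible(TRUE))
  g <- igraph::graph_from_data_frame(e[, c("child", "parent")], directed = TRUE)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    bad <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)]
    if (!length(bad)) { # self-loop case
      bad <- e$child[e$child == e$parent]
    }
    stop("cyclic ", paste(relations, collapse = "/"),
         " hierarchy; cycle involves term ", bad[1])
  }
  invisible(TRUE)
}

# Resolve ids through the alt_id table; unknown ids pass through.
resolve_term_id <- function(dag, id) {
  id <- normalize_term_id(id)
  hit <- !is.na(match(id, names(dag$alt_ids)))
  id[hit] <- unname(dag$alt_ids[id[hit]])
  id
}

#' Descendant closure of a term
#'
#' Repeatedly expands direct child terms over the given relation subset until
#' a fixed point is reached, mirroring an iterated direct-descendant query
#' against a GO browser. The root itself is not part of the result.
#'
#' @param dag a \code{term_dag}.
#' @param root a term id present in \code{dag} (alternative ids are resolved).
#' @param relations character subset of
#'   \code{c("is_a", "part_of", "regulates", "other")} to traverse.
#' @param include_obsolete keep obsolete terms in the closure? Default
#'   \code{FALSE}: obsolete terms carry no annotations and are skipped.
#' @return character vector of descendant term ids (unordered set, returned
#'   sorted for determinism).
#' @export
descendants <- function(dag, root, relations = c("is_a", "part_of"),
                        include_obsolete = FALSE) {
  stopifnot(inherits(dag, "term_dag"))
  root <- resolve_term_id(dag, root)
  if (!root %in% dag$terms$term_id) stop("unknown root term: ", root)
  e <- dag$edges[dag$edges$relation %in% relations, , drop = FALSE]
  if (!include_obsolete) {
    obsolete <- dag$terms$term_id[dag$terms$obsolete]
    e <- e[!(e$child %in% obsolete) & !(e$parent %in% obsolete), , drop = FALSE]
  }
  seen <- character()
  frontier <- root
  while (length(frontier)) {
    kids <- unique(e$child[e$parent %in% frontier])
    frontier <- setdiff(kids, c(seen, root))
    seen <- union(seen, frontier)
  }
  sort(seen)
}

#' Validate a curated term selection
#'
#' Checks that every curated term is the root or one of its descendants and
#' packages the selection with its category tags. Also emits a sufficiency
#' report: descendants of the root that are covered by no curated term's own
#' closure (the curated terms themselves included) are returned as the
#' \code{uncovered} attribute and raised as a warning, so a curator can see
#' whether the chosen terms subsume the full sub-hierarchy.
#'
#' @param dag a \code{term_dag}.
#' @param root root term id of the sub-hierarchy under study.
#' @param curated data.frame with columns \code{term_id} and \code{category}
#'   (category tags must be unique), or a named character vector
#'   \code{c(term_id = category)}.
#' @param relations relation subset passed to \code{\link{descendants}}.
#' @return object of class \code{term_selection}: list with \code{root_id}
#'   and \code{selection} (data.frame \code{term_id}, \code{label},
#'   \code{category}); attribute \code{uncovered} holds the sufficiency
#'   report.
#' @export
select_terms <- function(dag, root, curated,
                         relations = c("is_a", "part_of")) {
  stopifnot(inherits(dag, "term_dag"))
  if (is.character(curated) && !is.null(names(curated))) {
    curated <- data.frame(term_id = names(curated), category = unname(curated),
                          stringsAsFactors = FALSE)
  }
  if (!is.data.frame(curated) || !all(c("term_id", "category") %in% names(curated)))
    stop("curated must be a data.frame with columns term_id and category")
  if (!nrow(curated)) stop("curated selection is empty")
  if (anyDuplicated(curated$category))
    stop("duplicate category tag(s): ",
         paste(unique(curated$category[duplicated(curated$category)]),
               collapse = ", "))

  root <- resolve_term_id(dag, root)
  ids <- resolve_term_id(dag, curated$term_id)
  unknown <- setdiff(ids, dag$terms$term_id)
  if (length(unknown))
    stop("curated term(s) not in ontology: ", paste(unknown, collapse = ", "))

  desc <- descendants(dag, root, relations = relations)
  outside <- ids[!(ids %in% c(root, desc))]
  if (length(outside))
    stop("curated term(s) not descending from ", root, ": ",
         paste(outside, collapse = ", "))

  covered <- unique(unlist(lapply(ids, function(t)
    c(t, descendants(dag, t, relations = relations)))))
  uncovered <- setdiff(desc, covered)
  if (length(uncovered))
    warning(length(uncovered), " descendant term(s) of ", root,
            " not covered by the curated selection: ",
            paste(uncovered, collapse = ", "))

  labels <- dag$terms$name[match(ids, dag$terms$term_id)]
  sel <- data.frame(term_id = ids, label = labels,
                    category = curated$category, stringsAsFactors = FALSE)
  structure(list(root_id = root, selection = sel),
            class = "term_selection", uncovered = uncovered)
}

#' @export
print.term_dag <- function(x, ...) {
  cat("term_dag:", nrow(x$terms), "terms,", nrow(x$edges), "edges (",
      sum(x$terms$obsolete), "obsolete )\n")
  invisible(x)
}

#' @export
print.term_selection <- function(x, ...) {
  cat("term_selection rooted at", x$root_id, "with",
      nrow(x$selection), "terms\n")
  print(x$selection, ...)
  invisible(x)
}
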