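#' @title Venn partitioning and exclusivity filtering of gene-set families
#' @name setops
NULL

#' Full Venn partition of a family of gene sets
#'
#' Decomposes the union of the input sets into the \eqn{2^k - 1} disjoint
#' Venn cells of the k categories. Cells are indexed by their category
#' subset, labelled with the member categories joined by \code{"&"} in input
#' order; empty cells are retained. Gene ids are compared by exact string
#' equality after whitespace trimming (case preserved: Arabidopsis AGI codes
#' are case-significant by convention).
#'
#' @param family named list of character vectors, one gene set per category.
#' @return object of class \code{venn_partition}: list with
#'   \code{categories}, \code{cells} (named list over all non-empty category
#'   subsets) and \code{universe}.
#' @export
venn_partition <- function(family) {
  if (!length(family)) stop("at least one category is required")
  if (is.null(names(family)) || any(!nzchar(names(family))))
    stop("every category must be named")
  if (anyDuplicated(names(family)))
    stop("duplicate category name(s): ",
         paste(unique(names(family)[duplicated(names(family))]), collapse = ", "))

  cats <- names(family)
  k <- length(cats)
  family <- lapply(family, function(g) unique(trim(as.character(g))))
  universe <- sort(unique(unlist(family, use.names = FALSE)))

  # membership bitmask per gene
  member <- vapply(family, function(set) universe %in% set,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  mask <- as.integer(member %*% (2^(seq_len(k) - 1)))

  cells <- vector("list", 2^k - 1)
  labels <- character(2^k - 1)
  for (m in seq_len(2^k - 1)) {
    in_subset <- bitwAnd(m, 2^(seq_len(k) - 1)) > 0
    labels[m] <- paste(cats[in_subset], collapse = "&")
    cells[[m]] <- universe[mask == m]
  }
  names(cells) <- labels
  structure(list(categories = cats, cells = cells, universe = universe),
            class = "venn_partition")
}

cell_subsets <- function(partition) {
  k <- length(partition$categories)
  lapply(seq_len(2^k - 1), function(m)
    partition$categories[bitwAnd(m, 2^(seq_len(k) - 1)) > 0])
}

#' Category-exclusive genes
#'
#' Extracts, for each leaf category, the genes annotated to that leaf and to
#' no other leaf. Non-leaf categories (e.g. a parent term such as "response
#' to UV" alongside its UV-A/B/C children) do not participate in the
#' exclusivity test: a gene in one leaf plus a parent is still exclusive to
#' that leaf. Genes belonging only to non-leaf categories are reported
#' separately as \code{parent_only}.
#'
#' @param partition a \code{venn_partition}.
#' @param leaf_categories character vector of the categories subject to the
#'   exclusivity test; must be a subset of the partition's categories.
#' @return list with \code{exclusive} (named list over leaf categories) and
#'   \code{parent_only} (character vector).
#' @export
exclusive_genes <- function(partition, leaf_categories) {
  stopifnot(inherits(partition, "venn_partition"))
  unknown <- setdiff(leaf_categories, partition$categories)
  if (length(unknown))
    stop("unknown categor(ies): ", paste(unknown, collapse = ", "))

  subsets <- cell_subsets(partition)
  exclusive <- stats::setNames(
    vector("list", length(leaf_categories)), leaf_categories)
  for (lc in leaf_categories) exclusive[[lc]] <- character()
  parent_only <- character()

  for (i in seq_along(subsets)) {
    leaves_here <- intersect(subsets[[i]], leaf_categories)
    genes <- partition$cells[[i]]
    if (!length(genes)) next
    if (length(leaves_here) == 1L) {
      exclusive[[leaves_here]] <- sort(union(exclusive[[leaves_here]], genes))
    } else if (length(leaves_here) == 0L) {
      parent_only <- union(parent_only, genes)
    }
    # genes touching >1 leaf are excluded from every output set
  }
  list(exclusive = exclusive, parent_only = sort(parent_only))
}

#' @export
print.venn_partition <- function(x, ...) {
  sizes <- lengths(x$cells)
  cat("venn_partition over", length(x$categories), "categories;",
      length(x$universe), "genes in", sum(sizes > 0), "non-empty cells\n")
  invisible(x)
}

#' Cell-size summary of a Venn partition
#'
#' @param partition a \code{venn_partition}.
#' @return data.frame (\code{cell}, \code{n_genes}) over all cells.
#' @export
venn_cell_sizes <- function(partition) {
  data.frame(cell = names(partition$cells),
             n_genes = unname(lengths(partition$cells)),
             stringsAsFactors = FALSE)
}
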