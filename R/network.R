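#' @title Clique scoring of confidence-weighted interaction networks
#' @description Build a simple undirected protein-protein interaction network
#'   from a STRING-style edge list and score nodes by participation in dense
#'   cliques.
#' @name network
NULL

#' Construct a PPI network
#'
#' @param edges data.frame with columns \code{node_a}, \code{node_b},
#'   \code{score} (integer confidence on STRING's 0-1000 scale). Self-loops
#'   are dropped; duplicate undirected edges are collapsed keeping the
#'   maximum score.
#' @param nodes optional character vector of nodes; defaults to the edge
#'   endpoints. Extra isolated nodes may be supplied.
#' @return object of class \code{ppi_network}: list with \code{nodes}
#'   (character) and \code{edges} (data.frame \code{node_a}, \code{node_b},
#'   \code{score}).
#' @export
ppi_network <- function(edges, nodes = NULL) {
  stopifnot(all(c("node_a", "node_b", "score") %in% names(edges)))
  edges$node_a <- trim(as.character(edges$node_a))
  edges$node_b <- trim(as.character(edges$node_b))
  edges <- edges[edges$node_a != edges$node_b, , drop = FALSE]
  if (nrow(edges)) {
    a <- pmin(edges$node_a, edges$node_b)
    b <- pmax(edges$node_a, edges$node_b)
    edges <- data.frame(node_a = a, node_b = b, score = edges$score,
                        stringsAsFactors = FALSE)
    edges <- stats::aggregate(score ~ node_a + node_b, data = edges, FUN = max)
    edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(node_a = character(), node_b = character(),
                        score = numeric(), stringsAsFactors = FALSE)
  }
  nodes <- sort(unique(c(nodes, edges$node_a, edges$node_b)))
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' Load a STRING-style edge list
#'
#' Reads a whitespace- or tab-separated file with a header naming the two
#' endpoint columns (\code{protein1}/\code{protein2} or
#' \code{node_a}/\code{node_b}) and \code{combined_score}. Edges below
#' \code{min_score} are dropped; duplicates are collapsed keeping the
#' maximum score.
#'
#' @param path edge-list file.
#' @param min_score minimum combined score to retain an edge (STRING's
#'   "medium confidence" default of 400).
#' @return a \code{ppi_network}.
#' @export
load_ppi_edges <- function(path, min_score = 400) {
  if (!file.exists(path)) stop("cannot read edge file: ", path)
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#", quote = "")
  nm <- names(df)
  a_col <- intersect(c("protein1", "node_a"), nm)[1]
  b_col <- intersect(c("protein2", "node_b"), nm)[1]
  if (is.na(a_col) || is.na(b_col) || !"combined_score" %in% nm)
    stop("edge file needs columns protein1/protein2 (or node_a/node_b) ",
         "and combined_score")
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (anyNA(score))
    stop("non-numeric combined_score at data line ", which(is.na(score))[1],
         " of ", path)
  keep <- score >= min_score
  ppi_network(data.frame(node_a = df[[a_col]][keep],
                         node_b = df[[b_col]][keep],
                         score = score[keep], stringsAsFactors = FALSE))
}

ppi_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges[, c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  igraph::E(g)$score <- net$edges$score
  g
}

#' Clique-participation node scores
#'
#' For every node, counts all cliques (not only maximal ones) of size at
#' least \code{min_size} that contain it, on the score-thresholded graph.
#' This operationalizes "nodes of dense cliques": a node inside one K5
#' participates in C(4,2) triangles, C(4,3) 4-cliques and one 5-clique
#' through that K5 alone. The weighted degree (sum of incident scores
#' divided by 1000) is carried as tie-breaker.
#'
#' @param net a \code{ppi_network}.
#' @param min_size minimum clique size to count; must be >= 3.
#' @param max_maximal_cliques guard against pathological inputs: an error is
#'   raised if the graph has more maximal cliques than this cap.
#' @return data.frame (\code{node}, \code{clique_score},
#'   \code{weighted_degree}) sorted by score descending, then weighted
#'   degree, then node id.
#' @export
clique_node_scores <- function(net, min_size = 3, max_maximal_cliques = 1e5) {
  stopifnot(inherits(net, "ppi_network"))
  if (min_size < 3) stop("min_size must be >= 3")
  g <- ppi_igraph(net)
  counts <- stats::setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    n_max <- igraph::count_max_cliques(g)
    if (n_max > max_maximal_cliques)
      stop("graph has ", n_max, " maximal cliques, above the cap of ",
           max_maximal_cliques)
    cl <- igraph::cliques(g, min = min_size)
    for (clq in cl) {
      members <- names(clq)
      counts[members] <- counts[members] + 1L
    }
  }
  wdeg <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    s <- igraph::strength(g, weights = igraph::E(g)$score) / 1000
    wdeg[names(s)] <- s
  }
  out <- data.frame(node = net$nodes,
                    clique_score = unname(counts[net$nodes]),
                    weighted_degree = unname(wdeg[net$nodes]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$clique_score, -out$weighted_degree, out$node), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shortlist dense-clique hub candidates per category
#'
#' Within each category's gene pool, orders genes by clique score
#' (descending), weighted degree (descending), then gene id, and keeps the
#' top \code{top_n}. Pool genes absent from the network score 0 and sink to
#' the bottom.
#'
#' @param scores output of \code{\link{clique_node_scores}}.
#' @param pool named list, one gene set per category.
#' @param top_n maximum number of candidates per category (>= 1).
#' @return named list of gene character vectors in rank order.
#' @export
select_hub_candidates <- function(scores, pool, top_n) {
  if (top_n < 1) stop("top_n must be >= 1")
  lapply(pool, function(genes) {
    genes <- unique(as.character(genes))
    idx <- match(genes, scores$node)
    cs <- ifelse(is.na(idx), 0L, scores$clique_score[idx])
    wd <- ifelse(is.na(idx), 0, scores$weighted_degree[idx])
    ord <- order(-cs, -wd, genes)
    utils::head(genes[ord], top_n)
  })
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}
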