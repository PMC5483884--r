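# Brute-force oracles, kept independent of the implementation paths they
# check: reachability by boolean matrix iteration, Venn cells by per-gene
# membership classification, clique counts by subset enumeration, transfer
# by an exhaustive scan over (annotated gene, group, member) triples.

ext_fixture <- function(f) system.file("extdata", f, package = "orthoscreen")

# transitive descendant closure via repeated boolean matrix multiplication
reach_oracle <- function(dag, root, relations = c("is_a", "part_of"),
                         include_obsolete = FALSE) {
  ids <- dag$terms$term_id
  ok <- if (include_obsolete) ids else ids[!dag$terms$obsolete]
  e <- dag$edges[dag$edges$relation %in% relations &
                   dag$edges$child %in% ok & dag$edges$parent %in% ok, ,
                 drop = FALSE]
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(e)) A[cbind(e$parent, e$child)] <- 1
  R <- A
  repeat {
    R2 <- ((R + R %*% A) > 0) * 1
    if (identical(R2, R)) break
    R <- R2
  }
  sort(ids[R[root, ] > 0])
}

# Venn cells by classifying each gene's exact membership pattern
venn_oracle <- function(family) {
  cats <- names(family)
  family <- lapply(family, function(g) unique(trimws(g)))
  universe <- sort(unique(unlist(family)))
  lab <- vapply(universe, function(g) {
    paste(cats[vapply(family, function(s) g %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  split(universe, lab)
}

# per-node count of all cliques of size >= min_size, by subset enumeration
clique_oracle <- function(net, min_size = 3) {
  nodes <- net$nodes
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (nrow(net$edges)) {
    adj[cbind(net$edges$node_a, net$edges$node_b)] <- TRUE
    adj[cbind(net$edges$node_b, net$edges$node_a)] <- TRUE
  }
  counts <- setNames(integer(length(nodes)), nodes)
  for (k in seq(min_size, length(nodes))) {
    combs <- utils::combn(nodes, k)
    for (j in seq_len(ncol(combs))) {
      sub <- combs[, j]
      if (all(adj[sub, sub][upper.tri(diag(k))])) {
        counts[sub] <- counts[sub] + 1L
      }
    }
  }
  counts
}

# exhaustive triple-scan transfer at depth 0
transfer_oracle <- function(annotated_A, annotated_B, groups,
                            taxon_A, taxon_B) {
  ids <- unique(groups$group_id)
  pairs <- list(); new_A <- character(); new_B <- character()
  excluded <- character()
  for (id in ids) {
    m <- groups[groups$group_id == id, , drop = FALSE]
    a_all <- m$gene[m$taxon == taxon_A]
    b_all <- m$gene[m$taxon == taxon_B]
    a_ann <- intersect(a_all, annotated_A)
    b_ann <- intersect(b_all, annotated_B)
    if (!length(a_ann) && !length(b_ann)) next   # never reached by a query
    if (length(a_all) && length(b_all)) {
      for (a in a_ann) for (b in b_ann)
        pairs[[length(pairs) + 1L]] <- c(a, b)
      new_A <- union(new_A, setdiff(a_all, annotated_A))
      new_B <- union(new_B, setdiff(b_all, annotated_B))
    } else {
      excluded <- union(excluded, id)
    }
  }
  pairs <- unique(do.call(rbind, pairs))
  if (is.null(pairs)) pairs <- matrix(character(), ncol = 2)
  list(pairs = pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE],
       new_A = sort(new_A), new_B = sort(new_B),
       excluded = sort(excluded))
}

# random orthogroup table over two taxa plus bystander taxa
random_groups <- function(n_groups, n_genes, taxa = c("hsa", "ath", "osa")) {
  gid <- sprintf("RG%03d", seq_len(n_groups))
  rows <- lapply(gid, function(id) {
    k <- sample(1:4, 1)
    data.frame(group_id = id,
               taxon = sample(taxa, k, replace = TRUE),
               gene = sprintf("x%03d", sample.int(n_genes, k)),
               stringsAsFactors = FALSE)
  })
  out <- unique(do.call(rbind, rows))
  class(out) <- c("orthogroup_table", "data.frame")
  out
}

# random category -> gene-set family
random_family <- function(n_cat, n_genes, p = 0.3) {
  genes <- sprintf("gene%03d", seq_len(n_genes))
  sets <- lapply(seq_len(n_cat), function(i) genes[runif(n_genes) < p])
  names(sets) <- LETTERS[seq_len(n_cat)]
  sets
}
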