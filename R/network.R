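#' Restrict a gene list to identifiers known to a PPI database
#'
#' Genes whose identifiers are absent from the interaction database are
#' removed (they cannot take part in network construction); original
#' order is preserved and the removed count is attached as attribute
#' `"n_removed"`.
#'
#' @param genes Character vector of gene/protein identifiers.
#' @param known_ids Character vector or set of identifiers present in the
#'   database.
#' @return The filtered identifier vector.
#' @export
map_and_filter_ids <- function(genes, known_ids) {
  keep <- genes %in% known_ids
  out <- genes[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Build a pathological PPI network around selected genes
#'
#' Expands the selected nodes by one interaction step on the database
#' graph (every database node adjacent to a selected node is added) and
#' returns the database subgraph induced on the resulting node set — so
#' each added node sits one edge from a selected node, and all database
#' edges among the kept nodes are retained.
#'
#' @param selected Character vector of selected node names, all present
#'   in `db`.
#' @param db The database PPI graph (undirected igraph, named vertices).
#' @return The induced igraph subgraph.
#' @export
build_pathological_network <- function(selected, db) {
  stopifnot(igraph::is_igraph(db))
  if (length(selected) == 0L) {
    warning("empty selection: returning an empty graph")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  missing <- setdiff(selected, igraph::V(db)$name)
  if (length(missing)) {
    stop("selected node(s) not in database: ",
         paste(missing, collapse = ", "))
  }
  nb <- igraph::neighborhood(db, order = 1L, nodes = selected)
  keep <- sort(unique(igraph::V(db)$name[unique(unlist(nb))]))
  igraph::induced_subgraph(db, keep)
}

#' Betweenness centrality scores for all nodes
#'
#' Unnormalized shortest-path betweenness on an undirected graph: for each
#' node, the number of shortest paths between other node pairs passing
#' through it, each unordered pair counted once, endpoints excluded, with
#' fractional credit when a pair has several equally short paths. Nodes
#' with high betweenness mediate much of the information flow of the
#' network and are candidates for hub ("core") genes.
#'
#' @param g An undirected igraph graph with named vertices.
#' @param restrict_to Optional node names: scores are computed on the full
#'   graph (linker nodes still mediate paths) but only these nodes are
#'   reported, e.g. the originally selected genes of an expanded network.
#' @return A `data.frame(node, betweenness)` sorted by decreasing score,
#'   ties broken by node name.
#' @export
betweenness_scores <- function(g, restrict_to = NULL) {
  stopifnot(igraph::is_igraph(g))
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  if (!is.null(restrict_to)) b <- b[names(b) %in% restrict_to]
  out <- data.frame(node = names(b), betweenness = unname(b),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$betweenness, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Core-gene calling by the top-quantile betweenness rule
#'
#' Flags as core the `ceiling(top_fraction * n)` highest-betweenness
#' nodes; nodes tied with the boundary score are all included, so when
#' every score is equal every node is core.
#'
#' @param scores Output of [betweenness_scores()].
#' @param top_fraction Fraction of nodes called core (default 0.25).
#' @return `scores` with `rank` and `is_core` columns.
#' @export
core_genes <- function(scores, top_fraction = 0.25) {
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must lie in (0, 1]")
  }
  scores <- scores[order(-scores$betweenness, scores$node), , drop = FALSE]
  n <- nrow(scores)
  if (n == 0L) {
    scores$rank <- integer(0); scores$is_core <- logical(0)
    return(scores)
  }
  k <- ceiling(top_fraction * n)
  cutoff <- scores$betweenness[k]
  scores$rank <- seq_len(n)
  scores$is_core <- scores$betweenness >= cutoff
  rownames(scores) <- NULL
  scores
}
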