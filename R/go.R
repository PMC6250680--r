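#' Construct a gene-to-term annotation table
#'
#' @param terms Named list mapping term IDs to character vectors of
#'   annotated gene IDs.
#' @param universe Character vector of all genes under consideration;
#'   default the union of all annotated genes. Every annotated gene must
#'   belong to the universe.
#' @return An object of class `annotation_table`.
#' @export
annotation_table <- function(terms, universe = NULL) {
  stopifnot(is.list(terms), !is.null(names(terms)))
  terms <- lapply(terms, unique)
  if (is.null(universe)) universe <- sort(unique(unlist(terms)))
  extra <- setdiff(unlist(terms), universe)
  if (length(extra)) {
    stop("annotated genes outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  structure(list(terms = terms, universe = unique(universe)),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("annotation_table:", length(x$terms), "terms over",
      length(x$universe), "genes\n")
  invisible(x)
}

#' Term enrichment by the hypergeometric upper tail
#'
#' For each term, tests over-representation of the selected genes by the
#' hypergeometric upper-tail probability `P(X >= k)` of drawing `k` or
#' more term genes when sampling `n` genes from a universe of `N`
#' containing `K` term genes; q-values come from Benjamini-Hochberg
#' across all tested terms. The `ease` variant discounts one overlapping
#' gene (tests `P(X >= k)` computed with `k - 1`), the more conservative
#' score popularized by annotation servers.
#'
#' @param selected Character vector of selected genes (must lie in the
#'   annotation universe).
#' @param ann An [annotation_table()].
#' @param q_threshold Enrichment threshold on q (default 0.01).
#' @param ease Apply the one-gene discount (default `FALSE`).
#' @return A `data.frame` per term: `term`, `k`, `K`, `n`, `N`, `fold`,
#'   `p`, `q`, `enriched`, sorted by increasing p.
#' @export
enrich_terms <- function(selected, ann, q_threshold = 0.01, ease = FALSE) {
  stopifnot(inherits(ann, "annotation_table"))
  selected <- unique(selected)
  outside <- setdiff(selected, ann$universe)
  if (length(outside)) {
    stop("selected genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  if (length(selected) == 0L) {
    warning("empty selection: no terms tested")
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), fold = numeric(0),
                      p = numeric(0), q = numeric(0),
                      enriched = logical(0)))
  }
  N <- length(ann$universe); n <- length(selected)
  res <- do.call(rbind, lapply(names(ann$terms), function(tm) {
    K <- length(ann$terms[[tm]])
    k <- length(intersect(selected, ann$terms[[tm]]))
    keff <- if (ease) max(k - 1L, 0L) else k
    p <- if (keff == 0L) 1 else
      stats::phyper(keff - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N,
               fold = (k / n) / (K / N), p = min(p, 1),
               stringsAsFactors = FALSE)
  }))
  res$q <- benjamini_hochberg(res$p)
  res$enriched <- res$q < q_threshold
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Jaccard distance between two terms' gene sets
#'
#' Terms are compared by their commonly annotated genes:
#' `1 - |A intersect B| / |A union B|`.
#'
#' @param a,b Non-empty character vectors of gene IDs.
#' @return The distance in \[0, 1\].
#' @export
term_distance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("term_distance: gene sets must be non-empty")
  }
  1 - length(intersect(a, b)) / length(union(a, b))
}

#' Group enriched terms by shared-gene clustering
#'
#' Agglomerative hierarchical clustering with Ward linkage over the
#' pairwise Jaccard distances of the terms' annotated gene sets, so that
#' terms annotating largely the same genes merge into one functional
#' group. Cluster assignments at `k` groups (or a height cut `h`) are
#' returned alongside the full merge tree.
#'
#' @param terms Character vector of term IDs to cluster (at least 2 for a
#'   non-trivial tree), e.g. the enriched terms of [enrich_terms()].
#' @param ann An [annotation_table()] holding the terms' gene sets.
#' @param k Number of groups to cut the tree into (default
#'   `max(1, round(sqrt(n_terms)))`).
#' @param h Optional height cut overriding `k`.
#' @return A list of class `term_clustering`: `hclust` (the merge tree,
#'   `NULL` for a single term), `clusters` (named integer vector),
#'   `distance` (the `dist` object).
#' @export
cluster_terms <- function(terms, ann, k = NULL, h = NULL) {
  stopifnot(inherits(ann, "annotation_table"))
  missing <- setdiff(terms, names(ann$terms))
  if (length(missing)) {
    stop("unknown term(s): ", paste(missing, collapse = ", "))
  }
  if (length(terms) < 2L) {
    cl <- stats::setNames(rep(1L, length(terms)), terms)
    return(structure(list(hclust = NULL, clusters = cl, distance = NULL),
                     class = "term_clustering"))
  }
  m <- length(terms)
  d <- matrix(0, m, m, dimnames = list(terms, terms))
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      d[i, j] <- d[j, i] <- term_distance(ann$terms[[terms[i]]],
                                          ann$terms[[terms[j]]])
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  if (is.null(k)) k <- max(1L, round(sqrt(m)))
  cl <- if (!is.null(h)) stats::cutree(hc, h = h) else stats::cutree(hc, k = k)
  structure(list(hclust = hc, clusters = cl, distance = stats::as.dist(d)),
            class = "term_clustering")
}

#' Write a term merge tree in Newick format
#'
#' @param clustering A `term_clustering` from [cluster_terms()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_term_tree <- function(clustering, path) {
  stopifnot(inherits(clustering, "term_clustering"))
  if (is.null(clustering$hclust)) {
    stop("no merge tree: clustering holds fewer than 2 terms")
  }
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}
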