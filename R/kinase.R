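#' Kinase downstream node set
#'
#' Nodes within `max_degree` protein-protein interaction steps (shortest
#' path distance) of any seed kinase, seeds included — the candidate
#' downstream pathway of the kinase(s).
#'
#' @param g An undirected igraph PPI graph with named vertices.
#' @param seeds Seed kinase node names.
#' @param max_degree Maximum degrees of separation (default 2).
#' @return Character vector of downstream node names (sorted).
#' @export
downstream_nodes <- function(g, seeds, max_degree = 2) {
  stopifnot(igraph::is_igraph(g), max_degree >= 1)
  missing <- setdiff(seeds, igraph::V(g)$name)
  if (length(missing)) {
    stop("seed(s) not present in graph: ", paste(missing, collapse = ", "))
  }
  d <- igraph::distances(g, v = seeds)
  sort(colnames(d)[apply(d, 2L, min) <= max_degree])
}

#' Enrichment of phosphorylation changes in a kinase downstream set
#'
#' Compares the fraction of phosphorylation-changed proteins inside the
#' kinase downstream neighborhood with the fraction outside it by the
#' two-sided Fisher exact test. Only detected phosphoproteins enter the
#' table (`undetected` status is excluded), and the seed kinases
#' themselves are excluded by default — they are the hypothesis, not
#' evidence.
#'
#' @param g An undirected igraph PPI graph with named vertices.
#' @param seeds Seed kinase node names.
#' @param status Named character vector over (a superset of) the graph
#'   nodes with values `"changed"`, `"unchanged"` or `"undetected"`;
#'   nodes missing from `status` are treated as undetected.
#' @param max_degree Neighborhood radius (default 2).
#' @param include_seeds Count the seeds themselves in the inside stratum
#'   (default `FALSE`).
#' @return A list: `n_changed_in`, `n_detected_in`, `n_changed_out`,
#'   `n_detected_out`, `odds_ratio`, `p`. When a stratum holds no
#'   detected protein, `p` and `odds_ratio` are `NA` with a warning.
#' @export
downstream_enrichment <- function(g, seeds, status, max_degree = 2,
                                  include_seeds = FALSE) {
  inside <- downstream_nodes(g, seeds, max_degree)
  if (!include_seeds) inside <- setdiff(inside, seeds)
  nodes <- igraph::V(g)$name
  if (!include_seeds) nodes <- setdiff(nodes, seeds)
  st <- status[nodes]
  st[is.na(st)] <- "undetected"
  det <- st != "undetected"
  is_in <- nodes %in% inside
  n_ch_in <- sum(det & is_in & st == "changed")
  n_det_in <- sum(det & is_in)
  n_ch_out <- sum(det & !is_in & st == "changed")
  n_det_out <- sum(det & !is_in)
  out <- list(n_changed_in = n_ch_in, n_detected_in = n_det_in,
              n_changed_out = n_ch_out, n_detected_out = n_det_out,
              odds_ratio = NA_real_, p = NA_real_)
  if (n_det_in == 0L || n_det_out == 0L) {
    warning("empty stratum: no detected proteins ",
            if (n_det_in == 0L) "inside" else "outside",
            " the downstream set")
    return(out)
  }
  ft <- fisher_exact_two_sided(matrix(c(n_ch_in, n_det_in - n_ch_in,
                                        n_ch_out, n_det_out - n_ch_out),
                                      2, byrow = TRUE))
  out$odds_ratio <- ft$odds_ratio
  out$p <- ft$p.value
  out
}
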