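# Canonical dialect: TSV, mandatory header, UTF-8, '.' decimal separator.

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  d
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phosphopeptide reporter-intensity table
#'
#' Expects a TSV with metadata columns `peptide`, `protein`, `site`,
#' `fragment`, `confidence`, `has_itraq_label`, `shared_spectrum`,
#' followed by one intensity column per channel named `case_1`,
#' `case_2`, ..., `control_1`, ... (group taken from the prefix).
#' Negative or non-numeric intensities are rejected with the offending
#' line number.
#'
#' @param path TSV file path.
#' @return A `reporter_matrix`.
#' @export
read_phospho_table <- function(path) {
  meta_cols <- c("peptide", "protein", "site", "fragment", "confidence",
                 "has_itraq_label", "shared_spectrum")
  d <- read_tsv_checked(path, meta_cols)
  chan_cols <- setdiff(names(d), meta_cols)
  if (!length(chan_cols)) stop("no intensity columns in ", path)
  groups <- sub("_[0-9]+$", "", chan_cols)
  if (!all(groups %in% c("case", "control"))) {
    stop("channel columns must be named case_<i> / control_<i>")
  }
  if (nrow(d) == 0L) {
    warning("empty phospho table: ", path)
    return(reporter_matrix(d[meta_cols], matrix(0, 0, length(chan_cols)),
                           groups))
  }
  intens <- as.matrix(d[chan_cols])
  if (!is.numeric(intens) || anyNA(intens)) {
    bad <- which(apply(is.na(suppressWarnings(
      matrix(as.numeric(intens), nrow(d)))), 1L, any))[1]
    stop("non-numeric intensity at data line ", bad, " of ", path)
  }
  neg <- which(apply(intens < 0, 1L, any))
  if (length(neg)) {
    stop("negative intensity at data line ", neg[1], " of ", path)
  }
  reporter_matrix(d[meta_cols], intens, groups)
}

#' Write a reporter matrix as TSV
#'
#' Inverse of [read_phospho_table()].
#'
#' @param m A `reporter_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_phospho_table <- function(m, path) {
  stopifnot(inherits(m, "reporter_matrix"))
  intens <- as.data.frame(m$intensities)
  names(intens) <- paste0(m$groups, "_",
                          stats::ave(seq_along(m$groups), m$groups,
                                     FUN = seq_along))
  write_tsv(cbind(m$rows, intens), path)
}

#' Read a pre-counted exon inclusion/skipping table
#'
#' TSV columns: `gene`, `exon`, `group`, `replicate`, `inclusion`,
#' `skipping` (counts must be non-negative integers).
#'
#' @param path TSV file path.
#' @return An `ExonCounts` data frame.
#' @export
read_counts_table <- function(path) {
  d <- read_tsv_checked(path, c("gene", "exon", "group", "replicate",
                                "inclusion", "skipping"))
  for (cn in c("inclusion", "skipping")) {
    if (any(d[[cn]] < 0) || any(d[[cn]] != round(d[[cn]]))) {
      stop("column ", cn, " must hold non-negative integers in ", path)
    }
  }
  d
}

#' Read gene models
#'
#' TSV columns: `gene`, `exon`, `start`, `end` (0-based half-open,
#' non-overlapping, increasing within a gene); an optional `strand`
#' column is carried along for provenance but never used in counting.
#'
#' @param path TSV file path.
#' @return A gene-model data frame.
#' @export
read_gene_models <- function(path) {
  d <- read_tsv_checked(path, c("gene", "exon", "start", "end"))
  if (any(d$end <= d$start)) stop("gene model with end <= start in ", path)
  d
}

#' Read spliced alignments
#'
#' TSV columns: `read_id`, `gene`, `blocks`, where `blocks` is a
#' comma-separated list of `start-end` aligned blocks (0-based
#' half-open).
#'
#' @param path TSV file path.
#' @return An alignment data frame.
#' @export
read_alignments <- function(path) {
  d <- read_tsv_checked(path, c("read_id", "gene", "blocks"))
  lapply(d$blocks, parse_blocks)  # validates
  d
}

#' Convert BED12-style block definitions to block strings
#'
#' @param chrom_start Alignment start (0-based).
#' @param block_sizes,block_starts Comma-separated BED12 `blockSizes` and
#'   `blockStarts` fields (starts relative to `chrom_start`).
#' @return A `"start-end,start-end"` block string.
#' @export
bed12_blocks <- function(chrom_start, block_sizes, block_starts) {
  sizes <- as.integer(strsplit(block_sizes, ",")[[1]])
  starts <- chrom_start + as.integer(strsplit(block_starts, ",")[[1]])
  paste(sprintf("%d-%d", starts, starts + sizes), collapse = ",")
}

#' Read a PPI graph from an edge list or SIF file
#'
#' Edge-list files hold two tab-separated node columns (no header); SIF
#' files hold `node1 <interaction> node2` with the interaction type
#' ignored. Duplicate edges are collapsed and self-loops dropped with a
#' warning, preserving the simple-graph invariant.
#'
#' @param path Input file path.
#' @param format `"edgelist"` or `"sif"`.
#' @return An undirected simple igraph graph.
#' @export
read_graph <- function(path, format = c("edgelist", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  edges <- if (format == "sif") {
    if (ncol(d) < 3L) stop("SIF needs 3 columns: node1 type node2")
    d[, c(1L, 3L)]
  } else {
    if (ncol(d) < 2L) stop("edge list needs 2 columns")
    d[, 1:2]
  }
  loops <- edges[[1]] == edges[[2]]
  if (any(loops)) {
    warning(sum(loops), " self-loop line(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a graph as a two-column edge list
#'
#' @param g An igraph graph with named vertices.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph_edgelist <- function(g, path) {
  el <- igraph::as_edgelist(g)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-to-term annotation table
#'
#' TSV columns: `term`, `gene`; one row per annotation.
#'
#' @param path TSV file path.
#' @param universe Optional gene universe (default: all annotated genes).
#' @return An [annotation_table()].
#' @export
read_annotations <- function(path, universe = NULL) {
  d <- read_tsv_checked(path, c("term", "gene"))
  annotation_table(split(d$gene, d$term), universe)
}

#' Write an annotation table as TSV
#'
#' @param ann An [annotation_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_table"))
  d <- data.frame(term = rep(names(ann$terms), lengths(ann$terms)),
                  gene = unlist(ann$terms, use.names = FALSE))
  write_tsv(d, path)
}
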