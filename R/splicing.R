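#' Parse an aligned-block string
#'
#' Blocks are written `"start-end,start-end"` in 0-based half-open
#' coordinates, non-overlapping and increasing; the gap between
#' consecutive blocks is the inferred splice junction.
#'
#' @param blocks A block string.
#' @return A two-column integer matrix (`start`, `end`).
#' @export
parse_blocks <- function(blocks) {
  parts <- strsplit(strsplit(blocks, ",", fixed = TRUE)[[1]], "-",
                    fixed = TRUE)
  m <- do.call(rbind, lapply(parts, as.integer))
  colnames(m) <- c("start", "end")
  if (any(is.na(m)) || any(m[, 2] <= m[, 1])) {
    stop("malformed block string: ", blocks)
  }
  if (nrow(m) > 1L && any(m[-1L, 1] < m[-nrow(m), 2])) {
    stop("blocks must be non-overlapping and increasing: ", blocks)
  }
  m
}

#' Count inclusion and skipping reads for an internal exon
#'
#' Inclusion reads are those with at least 1 bp of aligned-block overlap
#' with the exon body. Skipping reads are those carrying a junction whose
#' gap runs from the annotated end of exon `i-1` to the annotated start of
#' exon `i+1`, both boundaries matched exactly (an optional `tolerance`
#' in bp relaxes the match). A read contributes at most once per category.
#'
#' @param model Gene model for one gene: `data.frame(start, end)` of
#'   0-based half-open exon coordinates, strictly increasing and
#'   non-overlapping.
#' @param alignments List of aligned-block matrices (see
#'   [parse_blocks()]), or a character vector of block strings.
#' @param exon_index Index of an internal exon (`1 < i < n_exons`).
#' @param tolerance Allowed boundary mismatch in bp (default 0: exact).
#' @return Named integer vector `c(inclusion = I, skipping = S)`.
#' @export
count_inclusion_skipping <- function(model, alignments, exon_index,
                                     tolerance = 0L) {
  stopifnot(all(c("start", "end") %in% names(model)))
  n <- nrow(model)
  if (exon_index <= 1L || exon_index >= n) {
    stop("skipping is defined only for internal exons (1 < i < ", n, ")")
  }
  if (is.character(alignments)) alignments <- lapply(alignments, parse_blocks)
  s_i <- model$start[exon_index]; e_i <- model$end[exon_index]
  junc_start <- model$end[exon_index - 1L]
  junc_end <- model$start[exon_index + 1L]
  incl <- 0L; skip <- 0L
  for (blk in alignments) {
    if (any(blk[, "start"] < e_i & blk[, "end"] > s_i)) incl <- incl + 1L
    if (nrow(blk) > 1L) {
      gaps_s <- blk[-nrow(blk), "end"]
      gaps_e <- blk[-1L, "start"]
      if (any(abs(gaps_s - junc_start) <= tolerance &
              abs(gaps_e - junc_end) <= tolerance)) {
        skip <- skip + 1L
      }
    }
  }
  c(inclusion = incl, skipping = skip)
}

#' Adjusted log2 skipping/inclusion ratio
#'
#' The per-exon splicing-change statistic: the log2 of the case group's
#' skipping/inclusion ratio adjusted to (divided by) the control group's
#' ratio. Requires all four counts to be at least 1; otherwise the exon is
#' not computable and `NA` is returned.
#'
#' @param s_case,i_case,s_ctrl,i_ctrl Skipping and inclusion read counts
#'   in the case and control groups.
#' @return `log2((s_case/i_case) / (s_ctrl/i_ctrl))`, or `NA_real_` when
#'   any count is 0.
#' @export
adjusted_log2_ratio <- function(s_case, i_case, s_ctrl, i_ctrl) {
  x <- c(s_case, i_case, s_ctrl, i_ctrl)
  if (any(x < 0)) stop("counts must be non-negative")
  if (any(x < 1)) return(NA_real_)
  log2((s_case / i_case) / (s_ctrl / i_ctrl))
}

#' Fisher test for one exon's 2x2 skipping table
#'
#' Builds the 2x2 contingency table (rows = groups, columns = skipping vs
#' inclusion reads) and applies the two-sided Fisher exact test. The
#' positive-integer rule: every cell must contain a positive integer for
#' the exon to be testable; otherwise `tested = FALSE` and no p-value is
#' assigned. Replicates should be summed within group before calling.
#'
#' @inheritParams adjusted_log2_ratio
#' @return A list: `tested`, `p` (NA when untested), `adjusted_log2`.
#' @export
test_exon <- function(s_case, i_case, s_ctrl, i_ctrl) {
  x <- c(s_case, i_case, s_ctrl, i_ctrl)
  if (any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers")
  }
  if (any(x < 1)) {
    return(list(tested = FALSE, p = NA_real_, adjusted_log2 = NA_real_))
  }
  ft <- fisher_exact_two_sided(matrix(c(s_case, i_case, s_ctrl, i_ctrl),
                                      2, byrow = TRUE))
  list(tested = TRUE, p = ft$p.value,
       adjusted_log2 = adjusted_log2_ratio(s_case, i_case, s_ctrl, i_ctrl))
}

#' Exon-skipping differential analysis over a counts table
#'
#' Sums replicate counts within each group, applies [test_exon()] per
#' exon, and calls significance by Benjamini-Hochberg across tested exons
#' only (exons failing the positive-integer rule are excluded before
#' adjustment, shrinking the family).
#'
#' @param counts `ExonCounts` data frame: `gene`, `exon`, `group`,
#'   `replicate`, `inclusion`, `skipping`.
#' @param case,control Group labels to compare (defaults `"case"`,
#'   `"control"`).
#' @param q_threshold Significance threshold on q (default 0.05).
#' @return A `SplicingResults` data frame: `gene`, `exon`,
#'   `adjusted_log2`, `p`, `q`, `tested`, `significant`.
#' @export
splicing_analysis <- function(counts, case = "case", control = "control",
                              q_threshold = 0.05) {
  need <- c("gene", "exon", "group", "inclusion", "skipping")
  stopifnot(all(need %in% names(counts)))
  counts <- counts[counts$group %in% c(case, control), , drop = FALSE]
  agg <- stats::aggregate(cbind(inclusion, skipping) ~ gene + exon + group,
                          data = counts, FUN = sum)
  ca <- agg[agg$group == case, ]
  co <- agg[agg$group == control, ]
  key <- function(d) paste(d$gene, d$exon)
  co <- co[match(key(ca), key(co)), ]
  res <- data.frame(gene = ca$gene, exon = ca$exon, stringsAsFactors = FALSE)
  tl <- Map(test_exon, ca$skipping, ca$inclusion, co$skipping, co$inclusion)
  res$adjusted_log2 <- vapply(tl, `[[`, numeric(1), "adjusted_log2")
  res$p <- vapply(tl, `[[`, numeric(1), "p")
  res$tested <- vapply(tl, `[[`, logical(1), "tested")
  call_significant(res, q_threshold)
}

#' Benjamini-Hochberg significance calling over tested exons
#'
#' @param results A `SplicingResults` data frame with `p` and `tested`.
#' @param q_threshold Significance threshold on q (default 0.05).
#' @return The input with `q` and `significant` columns; untested exons
#'   have `q = NA` and are never significant.
#' @export
call_significant <- function(results, q_threshold = 0.05) {
  results$q <- NA_real_
  idx <- which(results$tested)
  if (length(idx)) results$q[idx] <- benjamini_hochberg(results$p[idx])
  results$significant <- !is.na(results$q) & results$q < q_threshold
  results[order(results$gene, results$exon), , drop = FALSE]
}

#' Reads per kilobase per million mapped reads
#'
#' @param read_count Reads mapped to the feature.
#' @param feature_length_bp Feature length in bp (> 0).
#' @param library_size Total mapped reads in the library (> 0).
#' @return The RPKM value.
#' @export
rpkm <- function(read_count, feature_length_bp, library_size) {
  if (any(feature_length_bp <= 0) || any(library_size <= 0)) {
    stop("feature length and library size must be positive")
  }
  read_count / (feature_length_bp / 1e3) / (library_size / 1e6)
}

#' Exons significant in two comparisons
#'
#' Intersects the significant exon sets of two splicing analyses (for
#' example, two disease models each compared with its background strain)
#' and counts the distinct genes involved.
#'
#' @param results_a,results_b `SplicingResults` data frames.
#' @return A list: `exons` (`data.frame(gene, exon)` significant in
#'   both), `n_exons`, `n_genes`.
#' @export
overlap_significant <- function(results_a, results_b) {
  ka <- with(results_a[results_a$significant, ], paste(gene, exon))
  kb <- with(results_b[results_b$significant, ], paste(gene, exon))
  shared <- results_a[results_a$significant &
                        paste(results_a$gene, results_a$exon) %in% kb,
                      c("gene", "exon")]
  rownames(shared) <- NULL
  list(exons = shared, n_exons = nrow(shared),
       n_genes = length(unique(shared$gene)))
}

#' Rescue scoring of shared splicing changes
#'
#' An exon is recovered when it is significant in the disease-vs-control
#' comparison but no longer significant (q >= threshold) in the
#' treated-vs-control comparison. The default rule is non-significance
#' after treatment; `rule = "reversion"` instead requires the adjusted
#' log2 ratio to shrink to less than half its disease magnitude.
#'
#' @param disease_vs_ctrl,treated_vs_ctrl `SplicingResults` data frames.
#' @param shared `data.frame(gene, exon)` of exons to score (e.g. the
#'   `exons` element of [overlap_significant()]).
#' @param rule `"nonsignificance"` (default) or `"reversion"`.
#' @return A list: `recovered` (`data.frame(gene, exon)`), `n_recovered`,
#'   `fraction` (`NA` when `shared` is empty).
#' @export
recovery_analysis <- function(disease_vs_ctrl, treated_vs_ctrl, shared,
                              rule = c("nonsignificance", "reversion")) {
  rule <- match.arg(rule)
  if (nrow(shared) == 0L) {
    return(list(recovered = shared, n_recovered = 0L, fraction = NA_real_))
  }
  key <- function(d) paste(d$gene, d$exon)
  kd <- key(disease_vs_ctrl); kt <- key(treated_vs_ctrl); ks <- key(shared)
  if (!all(ks %in% kd) || !all(ks %in% kt)) {
    stop("shared exons must be present in both result sets")
  }
  dis <- disease_vs_ctrl[match(ks, kd), ]
  trt <- treated_vs_ctrl[match(ks, kt), ]
  rec <- if (rule == "nonsignificance") {
    dis$significant & !trt$significant
  } else {
    dis$significant & !is.na(trt$adjusted_log2) &
      abs(trt$adjusted_log2) < 0.5 * abs(dis$adjusted_log2)
  }
  recovered <- shared[rec, , drop = FALSE]
  rownames(recovered) <- NULL
  list(recovered = recovered, n_recovered = sum(rec),
       fraction = sum(rec) / nrow(shared))
}
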