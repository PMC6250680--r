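#' Filter phosphopeptide records before quantification
#'
#' Removes fragments belonging to peptides that lack an isobaric (iTRAQ)
#' label, share MS/MS spectra with other proteins, have a maximum channel
#' intensity below `min_intensity`, or were identified at confidence not
#' exceeding `min_confidence` (the acceptance rule is strictly greater
#' than, so `c == 0.95` at the default threshold is removed). Filter
#' counts are attached as attribute `"filter_counts"`.
#'
#' @param m A `reporter_matrix`.
#' @param min_intensity Low-intensity cutoff on a row's maximum channel
#'   intensity. Default `NULL` uses the 1% quantile of all intensities.
#' @param min_confidence Identification-confidence threshold (default
#'   0.95, strict).
#' @return The filtered `reporter_matrix`.
#' @export
filter_peptides <- function(m, min_intensity = NULL, min_confidence = 0.95) {
  stopifnot(inherits(m, "reporter_matrix"))
  if (is.null(min_intensity)) {
    min_intensity <- stats::quantile(m$intensities, 0.01, names = FALSE)
  }
  row_max <- apply(m$intensities, 1L, max)
  drop_label <- !m$rows$has_itraq_label
  drop_shared <- m$rows$shared_spectrum
  drop_conf <- !(m$rows$confidence > min_confidence)
  drop_int <- row_max < min_intensity
  keep <- !(drop_label | drop_shared | drop_conf | drop_int)
  out <- reporter_matrix(m$rows[keep, , drop = FALSE],
                         m$intensities[keep, , drop = FALSE], m$groups)
  attr(out, "truth") <- attr(m, "truth")
  attr(out, "filter_counts") <- c(no_label = sum(drop_label),
                                  shared_spectrum = sum(drop_shared),
                                  low_confidence = sum(drop_conf),
                                  low_intensity = sum(drop_int),
                                  kept = sum(keep))
  out
}

#' Reporter-channel bias correction
#'
#' Rescales each reporter channel so that all channel totals equal the
#' grand mean of the original totals, under the assumption that the total
#' signal of all channels should be equal. Relative intensities within a
#' channel are preserved; the operation is idempotent.
#'
#' @param m A `reporter_matrix` with a positive total in every channel.
#' @return The bias-corrected `reporter_matrix`.
#' @export
normalize_channels <- function(m) {
  stopifnot(inherits(m, "reporter_matrix"))
  totals <- colSums(m$intensities)
  if (any(totals <= 0)) stop("normalize_channels: channel with zero total")
  scaled <- sweep(m$intensities, 2L, mean(totals) / totals, `*`)
  out <- reporter_matrix(m$rows, scaled, m$groups)
  attr(out, "truth") <- attr(m, "truth")
  out
}

#' Fragment-level site quantity
#'
#' The quantity of a phosphopeptide fragment set is the geometric mean of
#' the signal intensities of the MS/MS fragments covering the
#' phosphorylation site.
#'
#' @param fragment_intensities Non-empty vector of positive intensities.
#' @return The geometric mean.
#' @export
fragment_site_quantity <- function(fragment_intensities) {
  x <- as.numeric(fragment_intensities)
  if (length(x) == 0L) stop("no fragment intensities")
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("fragment intensities must be positive")
  }
  exp(mean(log(x)))
}

#' Case/control peptide ratio
#'
#' The peptide ratio is the geometric mean of the per-case-channel ratios
#' to the control geometric mean -- equivalently the back-transform
#' `10^(mean log10 ratio)`, consistent with the log-normal intensity
#' model.
#'
#' @param case,control Positive intensity vectors for the two groups.
#' @return The ratio (case over control).
#' @export
peptide_ratio <- function(case, control) {
  case <- as.numeric(case); control <- as.numeric(control)
  if (!length(case) || !length(control) ||
      any(case <= 0) || any(control <= 0)) {
    stop("peptide_ratio needs positive intensities in both groups")
  }
  exp(mean(log(case)) - mean(log(control)))
}

#' Weighted protein/site ratio
#'
#' Aggregates peptide ratios into a protein- or site-level ratio by a
#' weighted geometric mean, `exp(sum(w * log(r)) / sum(w))`. Weights play
#' the role of the vendor "error factors": more reliable peptides pull the
#' aggregate harder.
#'
#' @param peptide_ratios Positive ratios.
#' @param weights Non-negative weights, not all zero; default uniform.
#' @return The weighted geometric mean ratio.
#' @export
protein_site_ratio <- function(peptide_ratios,
                               weights = rep(1, length(peptide_ratios))) {
  r <- as.numeric(peptide_ratios); w <- as.numeric(weights)
  if (length(r) != length(w)) stop("ratios and weights differ in length")
  if (any(r <= 0)) stop("ratios must be positive")
  if (any(w < 0) || sum(w) == 0) stop("weights must be >= 0, not all zero")
  exp(sum(w * log(r)) / sum(w))
}

#' Per-site channel quantities from a reporter matrix
#'
#' Collapses a (filtered, bias-corrected) reporter matrix to one quantity
#' per phospho-site and channel: fragment intensities are combined by
#' geometric mean within each peptide ([fragment_site_quantity()]), and
#' peptides covering the same site are combined by a weighted geometric
#' mean ([protein_site_ratio()] applied per channel). With
#' `weighting = "inverse_variance"` each peptide is weighted by the
#' inverse variance of its fragment log intensities (a stand-in for
#' vendor error factors); peptides with undefined variance fall back to
#' the uniform weight.
#'
#' @param m A `reporter_matrix`.
#' @param weighting `"inverse_variance"` (default) or `"uniform"`.
#' @return A list with `quant` (sites x channels matrix of positive
#'   quantities), `sites` (`data.frame(protein, site)` in matrix row
#'   order) and `groups` (per-channel labels).
#' @export
site_channel_quantities <- function(m,
                                    weighting = c("inverse_variance",
                                                  "uniform")) {
  stopifnot(inherits(m, "reporter_matrix"))
  weighting <- match.arg(weighting)
  if (any(m$intensities <= 0)) {
    stop("site quantification needs strictly positive intensities")
  }
  pep_key <- m$rows$peptide
  peps <- unique(pep_key)
  # geometric mean over fragments, per peptide and channel
  logint <- log(m$intensities)
  pep_quant <- t(vapply(peps, function(p) {
    exp(colMeans(logint[pep_key == p, , drop = FALSE]))
  }, numeric(ncol(m$intensities))))
  pep_w <- vapply(peps, function(p) {
    # residual noise only: variance across fragments within each channel
    v <- mean(apply(logint[pep_key == p, , drop = FALSE], 2L, stats::var))
    if (weighting == "uniform" || !is.finite(v) || v <= 0) 1 else 1 / v
  }, numeric(1))

  meta <- m$rows[match(peps, pep_key), c("protein", "site")]
  site_key <- paste(meta$protein, meta$site)
  sites <- unique(site_key)
  quant <- t(vapply(sites, function(s) {
    idx <- which(site_key == s)
    exp(colSums(pep_w[idx] * log(pep_quant[idx, , drop = FALSE])) /
          sum(pep_w[idx]))
  }, numeric(ncol(m$intensities))))
  rownames(quant) <- sites
  list(quant = quant,
       sites = meta[match(sites, site_key), , drop = FALSE],
       groups = m$groups)
}

#' Differential phosphorylation test across sites
#'
#' For each site, per-channel log ratios to the control geometric mean are
#' compared between case and control channels by Welch's test (the log
#' transform reflects the log-normal ratio model; Welch because groups are
#' heteroscedastic), and p-values are adjusted across all tested sites by
#' Benjamini-Hochberg. Sites with fewer than two channels in either group
#' are excluded.
#'
#' Total-signal channel scaling leaves a global ratio offset whenever the
#' true changes are asymmetric (more up- than down-regulated sites, or
#' vice versa). Under the standard assumption that most sites are
#' unchanged, `center_ratios = TRUE` (the default) removes that offset by
#' subtracting the median site log ratio from the case-channel log ratios
#' before testing.
#'
#' @param sq Output of [site_channel_quantities()].
#' @param alpha Significance threshold on the q-value (default 0.05).
#' @param center_ratios Apply median-ratio recentering (default `TRUE`).
#' @return A `data.frame` with one row per site: `protein`, `site`,
#'   `ratio` (case/control), `log2_ratio`, `p`, `q`, `significant`.
#' @export
site_differential_test <- function(sq, alpha = 0.05, center_ratios = TRUE) {
  case <- sq$groups == "case"; ctrl <- sq$groups == "control"
  if (sum(case) < 2L || sum(ctrl) < 2L) {
    stop("need >= 2 replicate channels per group")
  }
  lq <- log(sq$quant)
  ref <- rowMeans(lq[, ctrl, drop = FALSE])
  offset <- if (center_ratios && nrow(lq) > 1L) {
    stats::median(rowMeans(lq[, case, drop = FALSE]) - ref)
  } else 0
  res <- do.call(rbind, lapply(seq_len(nrow(lq)), function(i) {
    lr_case <- lq[i, case] - ref[i] - offset
    lr_ctrl <- lq[i, ctrl] - ref[i]
    wt <- welch_test(lr_case, lr_ctrl)
    data.frame(protein = sq$sites$protein[i], site = sq$sites$site[i],
               ratio = exp(mean(lr_case) - mean(lr_ctrl)),
               p = wt$p.value, stringsAsFactors = FALSE)
  }))
  res$log2_ratio <- log2(res$ratio)
  res$q <- benjamini_hochberg(res$p)
  res$significant <- res$q < alpha
  rownames(res) <- NULL
  res[, c("protein", "site", "ratio", "log2_ratio", "p", "q", "significant")]
}

#' End-to-end site quantification pipeline
#'
#' Convenience wrapper chaining [filter_peptides()],
#' [normalize_channels()], [site_channel_quantities()] and
#' [site_differential_test()].
#'
#' @inheritParams filter_peptides
#' @inheritParams site_channel_quantities
#' @inheritParams site_differential_test
#' @return The per-site results `data.frame` of
#'   [site_differential_test()].
#' @export
quantify_sites <- function(m, min_intensity = NULL, min_confidence = 0.95,
                           weighting = "inverse_variance", alpha = 0.05,
                           center_ratios = TRUE) {
  m <- filter_peptides(m, min_intensity, min_confidence)
  m <- normalize_channels(m)
  site_differential_test(site_channel_quantities(m, weighting), alpha,
                         center_ratios = center_ratios)
}
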