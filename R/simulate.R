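#' Derive a reproducible substream seed
#'
#' All simulators are pure functions of their configuration, including the
#' seed. Pipelines that run several stochastic stages from one master seed
#' derive one substream seed per stage with this helper, so any stage can be
#' re-run independently and reproduce its output.
#'
#' @param seed Master integer seed.
#' @param k Integer stream index (0, 1, 2, ...).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + 7919 * as.numeric(k)) %% 2147483647)
}

#' Configuration for the phosphoproteome simulator
#'
#' Describes a reporter-ion (iTRAQ-style) phosphoproteome experiment with
#' log-normally distributed intensities: each fragment intensity is
#' `channel_bias[k] * base_intensity * 2^(delta * is_case[k]) * exp(eps)`,
#' `eps ~ Normal(0, log_noise_sd^2)`. Spiked sites carry a planted log2
#' fold change `delta`; all other sites have `delta = 0`.
#'
#' @param n_proteins Number of proteins.
#' @param peptides_per_protein Phosphopeptides per protein; each peptide
#'   carries one distinct phospho-site.
#' @param fragments_per_peptide MS/MS fragments quantified per peptide.
#' @param n_channels_case,n_channels_control Reporter channels per group.
#' @param channel_bias Positive multiplier per channel (case channels
#'   first); length `n_channels_case + n_channels_control`. Default all 1.
#' @param base_intensity Baseline reporter intensity.
#' @param log_noise_sd Standard deviation of the natural-log intensity
#'   noise; must be > 0.
#' @param spiked_sites `data.frame(protein, site, delta)` of planted
#'   effects; `delta` is the true log2 fold change (case / control).
#' @param p_no_label,p_shared_spectrum,p_low_confidence Fractions of
#'   peptides flagged unlabeled, shared-spectrum, or given low
#'   identification confidence (0.5), to exercise the filtering stage.
#' @param seed Integer seed.
#' @return A validated config list of class `phospho_sim_config`.
#' @export
phospho_sim_config <- function(n_proteins = 100,
                               peptides_per_protein = 2,
                               fragments_per_peptide = 3,
                               n_channels_case = 3,
                               n_channels_control = 3,
                               channel_bias = NULL,
                               base_intensity = 1000,
                               log_noise_sd = 0.1,
                               spiked_sites = NULL,
                               p_no_label = 0,
                               p_shared_spectrum = 0,
                               p_low_confidence = 0,
                               seed = 1L) {
  n_chan <- n_channels_case + n_channels_control
  if (is.null(channel_bias)) channel_bias <- rep(1, n_chan)
  if (length(channel_bias) != n_chan || any(channel_bias <= 0)) {
    stop("channel_bias must hold one positive multiplier per channel")
  }
  if (log_noise_sd <= 0) stop("log_noise_sd must be > 0")
  if (n_channels_case < 1 || n_channels_control < 1) {
    stop("need at least one channel per group")
  }
  if (base_intensity <= 0) stop("base_intensity must be > 0")
  if (is.null(spiked_sites)) {
    spiked_sites <- data.frame(protein = character(0), site = character(0),
                               delta = numeric(0))
  }
  stopifnot(all(c("protein", "site", "delta") %in% names(spiked_sites)))
  structure(list(n_proteins = as.integer(n_proteins),
                 peptides_per_protein = as.integer(peptides_per_protein),
                 fragments_per_peptide = as.integer(fragments_per_peptide),
                 n_channels_case = as.integer(n_channels_case),
                 n_channels_control = as.integer(n_channels_control),
                 channel_bias = channel_bias,
                 base_intensity = base_intensity,
                 log_noise_sd = log_noise_sd,
                 spiked_sites = spiked_sites,
                 p_no_label = p_no_label,
                 p_shared_spectrum = p_shared_spectrum,
                 p_low_confidence = p_low_confidence,
                 seed = as.integer(seed)),
            class = "phospho_sim_config")
}

#' Simulate a reporter-ion phosphopeptide intensity matrix
#'
#' @param cfg A [phospho_sim_config()].
#' @return A `reporter_matrix`: list with `rows` (fragment-level metadata:
#'   peptide, protein, site, confidence, has_itraq_label, shared_spectrum),
#'   `intensities` (fragments x channels), and `groups` (`"case"` /
#'   `"control"` per channel). The planted truth is attached as attribute
#'   `"truth"` (`data.frame(protein, site, delta)` for every site).
#' @export
simulate_phospho <- function(cfg) {
  stopifnot(inherits(cfg, "phospho_sim_config"))
  withr::with_seed(cfg$seed, {
    prot <- sprintf("P%04d", seq_len(cfg$n_proteins))
    grid <- expand.grid(fragment = seq_len(cfg$fragments_per_peptide),
                        pep = seq_len(cfg$peptides_per_protein),
                        protein = prot, stringsAsFactors = FALSE)
    grid$site <- sprintf("S%d", grid$pep * 100L)
    grid$peptide <- paste0(grid$protein, "_pep", grid$pep)
    n_frag <- nrow(grid)
    n_chan <- cfg$n_channels_case + cfg$n_channels_control
    groups <- rep(c("case", "control"),
                  c(cfg$n_channels_case, cfg$n_channels_control))

    key <- paste(grid$protein, grid$site)
    skey <- paste(cfg$spiked_sites$protein, cfg$spiked_sites$site)
    delta <- cfg$spiked_sites$delta[match(key, skey)]
    delta[is.na(delta)] <- 0

    eps <- matrix(stats::rnorm(n_frag * n_chan, sd = cfg$log_noise_sd),
                  nrow = n_frag)
    fc <- outer(delta, as.numeric(groups == "case"))  # log2 effect per cell
    intens <- sweep(cfg$base_intensity * 2^fc * exp(eps), 2L,
                    cfg$channel_bias, `*`)
    colnames(intens) <- paste0(groups, "_", stats::ave(seq_len(n_chan),
                                                       groups, FUN = seq_along))

    # peptide-level quality flags, constant across a peptide's fragments
    peps <- unique(grid$peptide)
    flag <- function(p) stats::runif(length(peps)) < p
    no_label <- flag(cfg$p_no_label)
    shared <- flag(cfg$p_shared_spectrum)
    low_conf <- flag(cfg$p_low_confidence)
    i <- match(grid$peptide, peps)
    rows <- data.frame(peptide = grid$peptide, protein = grid$protein,
                       site = grid$site, fragment = grid$fragment,
                       confidence = ifelse(low_conf[i], 0.5, 0.99),
                       has_itraq_label = !no_label[i],
                       shared_spectrum = shared[i],
                       stringsAsFactors = FALSE)

    truth <- unique(data.frame(protein = grid$protein, site = grid$site,
                               delta = delta, stringsAsFactors = FALSE))
    m <- reporter_matrix(rows, intens, groups)
    attr(m, "truth") <- truth
    m
  })
}

#' Construct a reporter matrix
#'
#' @param rows Fragment-level metadata `data.frame` with columns `peptide`,
#'   `protein`, `site`, `confidence`, `has_itraq_label`, `shared_spectrum`.
#' @param intensities Numeric matrix, one row per metadata row, one column
#'   per reporter channel; all values must be >= 0.
#' @param groups Character vector (`"case"`/`"control"`), one per channel.
#' @return An object of class `reporter_matrix`.
#' @export
reporter_matrix <- function(rows, intensities, groups) {
  intensities <- as.matrix(intensities)
  if (nrow(rows) != nrow(intensities)) {
    stop("metadata and intensity matrix disagree on row count")
  }
  if (length(groups) != ncol(intensities)) {
    stop("one group label per channel required")
  }
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (!all(groups %in% c("case", "control"))) {
    stop("groups must be 'case' or 'control'")
  }
  structure(list(rows = rows, intensities = intensities,
                 groups = as.character(groups)),
            class = "reporter_matrix")
}

#' @export
print.reporter_matrix <- function(x, ...) {
  cat("reporter_matrix:", nrow(x$rows), "fragments,",
      length(unique(x$rows$peptide)), "peptides,",
      ncol(x$intensities), "channels (",
      sum(x$groups == "case"), "case /", sum(x$groups == "control"),
      "control )\n")
  invisible(x)
}

#' Configuration for the exon-skipping count simulator
#'
#' Per exon and replicate, inclusion reads `I ~ Poisson(depth * psi)` and
#' skipping reads `S ~ Poisson(depth * (1 - psi))`, where `psi` is the
#' exon's inclusion level (PSI). Spiked exons use `psi_case` in the case
#' group only, planting a known splicing change.
#'
#' @param n_genes,exons_per_gene Gene-model dimensions; genes are named
#'   `G0001`, `G0002`, ...
#' @param depth Expected reads per exon locus.
#' @param psi Baseline inclusion level, strictly in (0, 1).
#' @param spiked_exons `data.frame(gene, exon, psi_case)` of planted
#'   inclusion changes (case group only).
#' @param replicates_per_group Biological replicates per group (default 3).
#' @param seed Integer seed.
#' @return A validated config list of class `splicing_sim_config`.
#' @export
splicing_sim_config <- function(n_genes = 100, exons_per_gene = 5,
                                depth = 100, psi = 0.8,
                                spiked_exons = NULL,
                                replicates_per_group = 3, seed = 1L) {
  if (psi <= 0 || psi >= 1) stop("psi must lie strictly in (0, 1)")
  if (depth <= 0) stop("depth must be positive")
  if (is.null(spiked_exons)) {
    spiked_exons <- data.frame(gene = character(0), exon = integer(0),
                               psi_case = numeric(0))
  }
  stopifnot(all(c("gene", "exon", "psi_case") %in% names(spiked_exons)))
  if (nrow(spiked_exons) &&
      (any(spiked_exons$psi_case <= 0) || any(spiked_exons$psi_case >= 1))) {
    stop("psi_case must lie strictly in (0, 1)")
  }
  structure(list(n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 depth = depth, psi = psi, spiked_exons = spiked_exons,
                 replicates_per_group = as.integer(replicates_per_group),
                 seed = as.integer(seed)),
            class = "splicing_sim_config")
}

#' Simulate per-exon inclusion/skipping read counts
#'
#' @param cfg A [splicing_sim_config()].
#' @return An `ExonCounts` data frame: `gene`, `exon`, `group`, `replicate`,
#'   `inclusion`, `skipping`, with the planted per-exon PSI table attached
#'   as attribute `"truth"`.
#' @export
simulate_splicing_counts <- function(cfg) {
  stopifnot(inherits(cfg, "splicing_sim_config"))
  withr::with_seed(cfg$seed, {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    base <- expand.grid(exon = seq_len(cfg$exons_per_gene), gene = genes,
                        stringsAsFactors = FALSE)[, c("gene", "exon")]
    key <- paste(base$gene, base$exon)
    skey <- paste(cfg$spiked_exons$gene, cfg$spiked_exons$exon)
    psi_case <- cfg$spiked_exons$psi_case[match(key, skey)]
    base$psi_control <- cfg$psi
    base$psi_case <- ifelse(is.na(psi_case), cfg$psi, psi_case)

    out <- do.call(rbind, lapply(c("case", "control"), function(gr) {
      psi <- if (gr == "case") base$psi_case else base$psi_control
      do.call(rbind, lapply(seq_len(cfg$replicates_per_group), function(r) {
        data.frame(gene = base$gene, exon = base$exon, group = gr,
                   replicate = r,
                   inclusion = stats::rpois(nrow(base), cfg$depth * psi),
                   skipping = stats::rpois(nrow(base), cfg$depth * (1 - psi)),
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(out) <- NULL
    attr(out, "truth") <- base
    out
  })
}

#' Simulate gene models and spliced alignments
#'
#' Emits non-overlapping exon models (0-based half-open coordinates; exon
#' length 100 bp, introns 100 bp) and reads that either lie within an
#' internal exon (inclusion evidence) or carry a gap joining the annotated
#' end of exon i-1 to the start of exon i+1 (skipping evidence), in
#' proportions `psi : (1 - psi)`. Spiked exons use their `psi_case`.
#' Because a skipping read's two blocks lie inside the flanking exons, it
#' also counts as inclusion evidence for those exons; the returned ground
#' truth accounts for this.
#'
#' @param cfg A [splicing_sim_config()] with `exons_per_gene >= 3`.
#' @return A list with `models` (`gene`, `exon`, `start`, `end`),
#'   `alignments` (`read_id`, `gene`, `blocks` as `"start-end,start-end"`),
#'   and `truth` (`gene`, `exon`, `inclusion`, `skipping`) for internal
#'   exons.
#' @export
simulate_spliced_reads <- function(cfg) {
  stopifnot(inherits(cfg, "splicing_sim_config"))
  if (cfg$exons_per_gene < 3L) {
    stop("skipping needs flanking exons: exons_per_gene must be >= 3")
  }
  exon_len <- 100L; intron_len <- 100L; read_len <- 50L; anchor <- 30L
  withr::with_seed(cfg$seed, {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    starts <- (seq_len(cfg$exons_per_gene) - 1L) * (exon_len + intron_len)
    models <- do.call(rbind, lapply(genes, function(g) {
      data.frame(gene = g, exon = seq_len(cfg$exons_per_gene),
                 start = starts, end = starts + exon_len,
                 stringsAsFactors = FALSE)
    }))
    skey <- paste(cfg$spiked_exons$gene, cfg$spiked_exons$exon)

    aln <- list(); truth <- list(); rid <- 0L
    for (g in genes) {
      n_ex <- cfg$exons_per_gene
      incl <- integer(n_ex); skip <- integer(n_ex)
      blocks <- character(0)
      for (i in 2:(n_ex - 1L)) {
        psi <- cfg$psi
        hit <- match(paste(g, i), skey)
        if (!is.na(hit)) psi <- cfg$spiked_exons$psi_case[hit]
        n_reads <- stats::rpois(1L, cfg$depth)
        n_in <- stats::rbinom(1L, n_reads, psi)
        n_sk <- n_reads - n_in
        s_i <- starts[i]; e_i <- s_i + exon_len
        if (n_in > 0) {
          rs <- s_i + sample.int(exon_len - read_len + 1L, n_in,
                                 replace = TRUE) - 1L
          blocks <- c(blocks, sprintf("%d-%d", rs, rs + read_len))
        }
        if (n_sk > 0) {
          e_prev <- starts[i - 1L] + exon_len
          s_next <- starts[i + 1L]
          blocks <- c(blocks, rep(sprintf("%d-%d,%d-%d",
                                          e_prev - anchor, e_prev,
                                          s_next, s_next + anchor), n_sk))
        }
        incl[i] <- incl[i] + n_in
        skip[i] <- n_sk
        # a skipping read's blocks overlap the two flanking exons
        incl[i - 1L] <- incl[i - 1L] + n_sk
        incl[i + 1L] <- incl[i + 1L] + n_sk
      }
      if (length(blocks)) {
        aln[[g]] <- data.frame(
          read_id = sprintf("r%07d", rid + seq_along(blocks)),
          gene = g, blocks = blocks, stringsAsFactors = FALSE)
        rid <- rid + length(blocks)
      }
      internal <- 2:(n_ex - 1L)
      truth[[g]] <- data.frame(gene = g, exon = internal,
                               inclusion = incl[internal],
                               skipping = skip[internal],
                               stringsAsFactors = FALSE)
    }
    list(models = models,
         alignments = do.call(rbind, c(aln, list(make.row.names = FALSE))),
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  })
}

#' Configuration for the PPI-graph simulator
#'
#' An Erdos-Renyi random graph in which nodes within `max_degree_sep`
#' interaction steps of the seed kinases are phosphorylation-"changed" with
#' probability `p_changed_in`, and all other nodes with `p_changed_out`;
#' equal probabilities give a planted null for the downstream-enrichment
#' test.
#'
#' @param n_nodes,edge_prob Erdos-Renyi parameters.
#' @param seed_kinases Node names (or integer indices) of the seed
#'   kinases; default the first two nodes.
#' @param max_degree_sep Neighborhood radius (default 2).
#' @param p_changed_in,p_changed_out Probability that a node inside /
#'   outside the downstream set is "changed".
#' @param p_undetected Probability a node is "undetected" (excluded from
#'   enrichment tables); default 0.
#' @param seed Integer seed.
#' @return A validated config list of class `network_sim_config`.
#' @export
network_sim_config <- function(n_nodes = 200, edge_prob = 0.02,
                               seed_kinases = NULL, max_degree_sep = 2,
                               p_changed_in = 0.5, p_changed_out = 0.5,
                               p_undetected = 0, seed = 1L) {
  if (edge_prob <= 0 || edge_prob >= 1) stop("edge_prob must lie in (0, 1)")
  for (p in c(p_changed_in, p_changed_out, p_undetected)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  if (is.null(seed_kinases)) seed_kinases <- 1:2
  structure(list(n_nodes = as.integer(n_nodes), edge_prob = edge_prob,
                 seed_kinases = seed_kinases,
                 max_degree_sep = as.integer(max_degree_sep),
                 p_changed_in = p_changed_in, p_changed_out = p_changed_out,
                 p_undetected = p_undetected, seed = as.integer(seed)),
            class = "network_sim_config")
}

#' Simulate a PPI graph with a planted kinase-downstream effect
#'
#' @param cfg A [network_sim_config()].
#' @return A list with `graph` (igraph), `status` (named character vector:
#'   `"changed"`, `"unchanged"` or `"undetected"`), `seeds` (seed-kinase
#'   node names) and `downstream` (names of nodes within `max_degree_sep`
#'   of a seed, seeds included).
#' @export
simulate_ppi <- function(cfg) {
  stopifnot(inherits(cfg, "network_sim_config"))
  withr::with_seed(cfg$seed, {
    g <- igraph::sample_gnp(cfg$n_nodes, cfg$edge_prob, directed = FALSE)
    igraph::V(g)$name <- sprintf("N%04d", seq_len(cfg$n_nodes))
    seeds <- cfg$seed_kinases
    if (is.numeric(seeds)) seeds <- sprintf("N%04d", as.integer(seeds))
    missing <- setdiff(seeds, igraph::V(g)$name)
    if (length(missing)) {
      stop("seed kinase(s) not in graph: ", paste(missing, collapse = ", "))
    }
    inside <- downstream_nodes(g, seeds, cfg$max_degree_sep)
    nodes <- igraph::V(g)$name
    p <- ifelse(nodes %in% inside, cfg$p_changed_in, cfg$p_changed_out)
    status <- ifelse(stats::runif(cfg$n_nodes) < p, "changed", "unchanged")
    und <- stats::runif(cfg$n_nodes) < cfg$p_undetected
    status[und] <- "undetected"
    names(status) <- nodes
    list(graph = g, status = status, seeds = seeds, downstream = inside)
  })
}

#' Configuration for the annotation-table simulator
#'
#' @param n_genes Universe size; genes are named `G0001`, ... to match
#'   [simulate_splicing_counts()].
#' @param n_terms Number of annotation terms.
#' @param genes_per_term_mean Mean number of genes annotated per term.
#' @param seed Integer seed.
#' @return A validated config list of class `annotation_sim_config`.
#' @export
annotation_sim_config <- function(n_genes = 100, n_terms = 20,
                                  genes_per_term_mean = 10, seed = 1L) {
  if (n_terms < 1) stop("n_terms must be >= 1")
  if (genes_per_term_mean <= 0) stop("genes_per_term_mean must be positive")
  structure(list(n_genes = as.integer(n_genes),
                 n_terms = as.integer(n_terms),
                 genes_per_term_mean = genes_per_term_mean,
                 seed = as.integer(seed)),
            class = "annotation_sim_config")
}

#' Simulate a gene-to-term annotation table
#'
#' Each term annotates a random gene subset whose size is
#' `1 + Poisson(genes_per_term_mean - 1)`, capped at the universe size.
#'
#' @param cfg An [annotation_sim_config()].
#' @return An [annotation_table()].
#' @export
simulate_annotations <- function(cfg) {
  stopifnot(inherits(cfg, "annotation_sim_config"))
  withr::with_seed(cfg$seed, {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    sizes <- pmin(1L + stats::rpois(cfg$n_terms, cfg$genes_per_term_mean - 1),
                  cfg$n_genes)
    terms <- lapply(sizes, function(k) sort(sample(genes, k)))
    names(terms) <- sprintf("T%04d", seq_len(cfg$n_terms))
    annotation_table(terms, genes)
  })
}
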