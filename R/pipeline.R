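#' Configuration for the end-to-end demonstration pipeline
#'
#' Assembles the thresholds used by every stage together with the sizes
#' of the synthetic study the pipeline analyses: a phosphoproteome with
#' planted differential sites, two splicing comparisons (two disease
#' models against a shared background) with a common planted exon set of
#' which a fixed fraction is reverted in a "treated" group, a PPI graph
#' with a planted kinase-downstream enrichment, and a gene-to-term
#' annotation table with a few planted enriched terms.
#'
#' @param outdir Output directory for result tables and the manifest.
#' @param seed Master seed; per-stage substreams are derived with
#'   [derive_seed()].
#' @param q_splicing,q_go,alpha Significance thresholds for exon calling
#'   (0.05), term enrichment (0.01) and site testing (0.05).
#' @param confidence Peptide identification-confidence threshold (0.95).
#' @param top_fraction Core-gene betweenness quantile (0.25).
#' @param max_degree Kinase downstream radius in interaction steps (2).
#' @param n_genes,exons_per_gene,depth,psi,n_spiked_exons,psi_case,replicates
#'   Splicing-study dimensions: planted exons are exon 3 of genes
#'   `G0001..`, moved from `psi` to `psi_case` in the disease groups.
#' @param revert_fraction Fraction of the planted exons whose inclusion
#'   is restored in the treated group (default 0.4).
#' @param n_proteins,n_spiked_sites,delta,log_noise_sd,n_channels
#'   Phospho-study dimensions: planted sites carry log2 fold change
#'   `delta`; `n_channels` reporter channels per group.
#' @param ppi_nodes,ppi_edge_prob,p_changed_in,p_changed_out
#'   Kinase-study dimensions (two seed kinases).
#' @param n_terms,genes_per_term_mean,n_planted_terms Annotation-table
#'   dimensions; planted terms draw their genes from the spiked genes.
#' @return A config list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("phosphosplice_run_"),
                            seed = 1L,
                            q_splicing = 0.05, q_go = 0.01, alpha = 0.05,
                            confidence = 0.95, top_fraction = 0.25,
                            max_degree = 2L,
                            n_genes = 300L, exons_per_gene = 5L,
                            depth = 100, psi = 0.8,
                            n_spiked_exons = 50L, psi_case = 0.2,
                            replicates = 3L, revert_fraction = 0.4,
                            n_proteins = 200L, n_spiked_sites = 20L,
                            delta = 2, log_noise_sd = 0.1,
                            n_channels = 3L,
                            ppi_nodes = 250L, ppi_edge_prob = 0.015,
                            p_changed_in = 0.8, p_changed_out = 0.1,
                            n_terms = 40L, genes_per_term_mean = 8,
                            n_planted_terms = 4L) {
  cfg <- as.list(environment())
  thr <- c(q_splicing, q_go, alpha, confidence, top_fraction)
  if (any(thr <= 0) || any(thr > 1)) stop("thresholds must lie in (0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Run the end-to-end demonstration pipeline
#'
#' Executes all stages in dependency order on synthetic data with known
#' ground truth: phosphoproteome quantification and differential testing;
#' kinase-downstream enrichment on a PPI graph; exon-skipping analysis of
#' two disease models and a treated group, with overlap and rescue
#' scoring; GO-term enrichment of the splicing-significant genes with
#' Ward term grouping; and pathological-network construction with
#' betweenness core-gene ranking. All result tables are written as TSV
#' under `cfg$outdir` together with a JSON run manifest (package version,
#' seed, thresholds, stage counters, file digests). Runs are
#' deterministic: the same config and seed yield byte-identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return (Invisibly) a list with each stage's in-memory results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$outdir, f)

  ## -- phosphoproteome ----------------------------------------------------
  spiked_sites <- data.frame(
    protein = sprintf("P%04d", seq_len(cfg$n_spiked_sites)),
    site = "S100", delta = cfg$delta)
  pcfg <- phospho_sim_config(
    n_proteins = cfg$n_proteins, peptides_per_protein = 1,
    fragments_per_peptide = 3,
    n_channels_case = cfg$n_channels, n_channels_control = cfg$n_channels,
    log_noise_sd = cfg$log_noise_sd, spiked_sites = spiked_sites,
    seed = derive_seed(cfg$seed, 1))
  phospho <- quantify_sites(simulate_phospho(pcfg),
                            min_confidence = cfg$confidence,
                            alpha = cfg$alpha)
  write_tsv(phospho, out("phospho_sites.tsv"))

  ## -- kinase downstream enrichment ---------------------------------------
  ncfg <- network_sim_config(
    n_nodes = cfg$ppi_nodes, edge_prob = cfg$ppi_edge_prob,
    max_degree_sep = cfg$max_degree,
    p_changed_in = cfg$p_changed_in, p_changed_out = cfg$p_changed_out,
    seed = derive_seed(cfg$seed, 2))
  sim_ppi <- simulate_ppi(ncfg)
  kin <- downstream_enrichment(sim_ppi$graph, sim_ppi$seeds, sim_ppi$status,
                               max_degree = cfg$max_degree)
  write_tsv(as.data.frame(kin), out("kinase_enrichment.tsv"))

  ## -- exon skipping: two disease models and a treated group --------------
  spiked_genes <- sprintf("G%04d", seq_len(cfg$n_spiked_exons))
  spiked <- data.frame(gene = spiked_genes, exon = 3L,
                       psi_case = cfg$psi_case)
  n_revert <- round(cfg$revert_fraction * cfg$n_spiked_exons)
  spiked_treated <- spiked[-seq_len(n_revert), , drop = FALSE]
  scfg <- function(sp, k) splicing_sim_config(
    n_genes = cfg$n_genes, exons_per_gene = cfg$exons_per_gene,
    depth = cfg$depth, psi = cfg$psi, spiked_exons = sp,
    replicates_per_group = cfg$replicates, seed = derive_seed(cfg$seed, k))
  res_a <- splicing_analysis(simulate_splicing_counts(scfg(spiked, 3)),
                             q_threshold = cfg$q_splicing)
  res_b <- splicing_analysis(simulate_splicing_counts(scfg(spiked, 4)),
                             q_threshold = cfg$q_splicing)
  res_t <- splicing_analysis(simulate_splicing_counts(scfg(spiked_treated, 5)),
                             q_threshold = cfg$q_splicing)
  write_tsv(res_a, out("splicing_modelA.tsv"))
  write_tsv(res_b, out("splicing_modelB.tsv"))
  write_tsv(res_t, out("splicing_treated.tsv"))

  shared <- overlap_significant(res_a, res_b)
  write_tsv(shared$exons, out("shared_exons.tsv"))
  recov <- recovery_analysis(res_a, res_t, shared$exons)
  write_tsv(data.frame(n_shared = shared$n_exons,
                       n_shared_genes = shared$n_genes,
                       n_recovered = recov$n_recovered,
                       fraction_recovered = recov$fraction),
            out("recovery.tsv"))

  ## -- GO enrichment of splicing-significant genes ------------------------
  sig_genes <- sort(unique(res_a$gene[res_a$significant]))
  acfg <- annotation_sim_config(
    n_genes = cfg$n_genes, n_terms = cfg$n_terms,
    genes_per_term_mean = cfg$genes_per_term_mean,
    seed = derive_seed(cfg$seed, 6))
  ann <- simulate_annotations(acfg)
  # planted enriched terms: blocks of spiked genes, so the enrichment and
  # term-grouping stages have real signal to find
  planted <- withr::with_seed(derive_seed(cfg$seed, 7), {
    lapply(seq_len(cfg$n_planted_terms), function(i) {
      sort(sample(spiked_genes, min(12, length(spiked_genes))))
    })
  })
  names(planted) <- sprintf("T_planted%02d", seq_along(planted))
  ann <- annotation_table(c(ann$terms, planted), ann$universe)
  go <- enrich_terms(sig_genes, ann, q_threshold = cfg$q_go)
  write_tsv(go, out("go_enrichment.tsv"))
  enriched_terms <- go$term[go$enriched]
  clust <- NULL
  if (length(enriched_terms) >= 2L) {
    clust <- cluster_terms(enriched_terms, ann)
    write_term_tree(clust, out("go_term_tree.nwk"))
  }

  ## -- pathological network and core genes --------------------------------
  db <- withr::with_seed(derive_seed(cfg$seed, 8), {
    g <- igraph::sample_gnp(cfg$n_genes, 3 / cfg$n_genes, directed = FALSE)
    igraph::V(g)$name <- sprintf("G%04d", seq_len(cfg$n_genes))
    g
  })
  selected <- map_and_filter_ids(sig_genes, igraph::V(db)$name)
  net <- build_pathological_network(selected, db)
  scores <- core_genes(betweenness_scores(net, restrict_to = selected),
                       top_fraction = cfg$top_fraction)
  write_tsv(scores, out("network_scores.tsv"))

  ## -- manifest ------------------------------------------------------------
  files <- setdiff(list.files(cfg$outdir), "manifest.json")
  manifest <- list(
    package = "phosphosplice",
    version = as.character(utils::packageVersion("phosphosplice")),
    seed = cfg$seed,
    thresholds = cfg[c("q_splicing", "q_go", "alpha", "confidence",
                       "top_fraction", "max_degree")],
    counters = list(
      phospho_sites_tested = nrow(phospho),
      phospho_sites_significant = sum(phospho$significant),
      exons_tested = sum(res_a$tested),
      exons_significant_modelA = sum(res_a$significant),
      shared_exons = shared$n_exons,
      recovered_exons = recov$n_recovered,
      go_terms_enriched = length(enriched_terms),
      network_nodes = igraph::vcount(net),
      core_genes = sum(scores$is_core)),
    digests = as.list(tools::md5sum(file.path(cfg$outdir, sort(files)))))
  names(manifest$digests) <- sort(files)
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(phospho = phospho, kinase = kin,
                 splicing = list(modelA = res_a, modelB = res_b,
                                 treated = res_t),
                 shared = shared, recovery = recov, go = go,
                 clustering = clust, network = net, scores = scores,
                 manifest = manifest))
}
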