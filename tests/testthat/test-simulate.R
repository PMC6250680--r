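test_that("simulators are pure functions of their seed", {
  pc <- phospho_sim_config(n_proteins = 10, seed = 7)
  expect_identical(simulate_phospho(pc)$intensities,
                   simulate_phospho(pc)$intensities)

  sc <- splicing_sim_config(n_genes = 5, seed = 7)
  expect_identical(simulate_splicing_counts(sc), simulate_splicing_counts(sc))

  rc <- splicing_sim_config(n_genes = 3, exons_per_gene = 4, seed = 7)
  expect_identical(simulate_spliced_reads(rc), simulate_spliced_reads(rc))

  nc <- network_sim_config(n_nodes = 40, edge_prob = 0.1, seed = 7)
  s1 <- simulate_ppi(nc); s2 <- simulate_ppi(nc)
  expect_identical(igraph::as_edgelist(s1$graph),
                   igraph::as_edgelist(s2$graph))
  expect_identical(s1$status, s2$status)

  ac <- annotation_sim_config(n_genes = 30, n_terms = 5, seed = 7)
  expect_identical(simulate_annotations(ac)$terms,
                   simulate_annotations(ac)$terms)
})

test_that("phospho simulator recovers a planted effect in the noise-free limit", {
  cfg <- phospho_sim_config(
    n_proteins = 10, peptides_per_protein = 1, fragments_per_peptide = 3,
    log_noise_sd = 1e-6,
    spiked_sites = data.frame(protein = "P0003", site = "S100", delta = 1),
    seed = 3)
  m <- simulate_phospho(cfg)
  res <- site_differential_test(site_channel_quantities(m),
                                center_ratios = FALSE)
  expect_equal(res$log2_ratio[res$protein == "P0003"], 1, tolerance = 1e-3)
  expect_equal(max(abs(res$log2_ratio[res$protein != "P0003"])), 0,
               tolerance = 1e-3)
})

test_that("phospho simulator applies channel bias multiplicatively", {
  bias <- c(1, 2, 1, 1)
  cfg <- phospho_sim_config(n_proteins = 5, n_channels_case = 2,
                            n_channels_control = 2, channel_bias = bias,
                            log_noise_sd = 1e-9, seed = 1)
  m <- simulate_phospho(cfg)
  expect_equal(unname(colSums(m$intensities) / colSums(m$intensities)[1]),
               bias, tolerance = 1e-6)
})

test_that("splicing count simulator matches its Poisson means at high depth", {
  cfg <- splicing_sim_config(n_genes = 20, exons_per_gene = 4, depth = 1e5,
                             psi = 0.5, replicates_per_group = 1, seed = 9)
  d <- simulate_splicing_counts(cfg)
  expect_equal(sum(d$skipping) / sum(d$inclusion), 1, tolerance = 0.01)
})

test_that("planted PSI change forces the expected adjusted log2 ratio", {
  # psi 0.8 -> 0.2 plants log2((0.8/0.2) / (0.2/0.8)) = 4
  cfg <- splicing_sim_config(
    n_genes = 2, exons_per_gene = 3, depth = 2e5, psi = 0.8,
    spiked_exons = data.frame(gene = "G0001", exon = 2, psi_case = 0.2),
    replicates_per_group = 1, seed = 4)
  d <- simulate_splicing_counts(cfg)
  g1 <- d[d$gene == "G0001" & d$exon == 2, ]
  ca <- g1[g1$group == "case", ]; co <- g1[g1$group == "control", ]
  expect_equal(adjusted_log2_ratio(ca$skipping, ca$inclusion,
                                   co$skipping, co$inclusion),
               4, tolerance = 0.05)
})

test_that("read simulator ground truth matches the read counter exactly", {
  set.seed(100)
  for (rep in 1:20) {
    cfg <- splicing_sim_config(
      n_genes = sample(1:3, 1), exons_per_gene = sample(3:6, 1),
      depth = sample(10:60, 1), psi = runif(1, 0.2, 0.9),
      replicates_per_group = 1, seed = sample.int(1e6, 1))
    sim <- simulate_spliced_reads(cfg)
    for (g in unique(sim$models$gene)) {
      model <- sim$models[sim$models$gene == g, ]
      blocks <- sim$alignments$blocks[sim$alignments$gene == g]
      tg <- sim$truth[sim$truth$gene == g, ]
      for (r in seq_len(nrow(tg))) {
        cnt <- count_inclusion_skipping(model, blocks, tg$exon[r])
        expect_identical(unname(cnt),
                         c(tg$inclusion[r], tg$skipping[r]))
      }
    }
  }
})

test_that("psi = 1 limit yields no skipping reads", {
  cfg <- splicing_sim_config(n_genes = 2, exons_per_gene = 4, depth = 50,
                             psi = 1 - 1e-12, replicates_per_group = 1,
                             seed = 2)
  sim <- simulate_spliced_reads(cfg)
  expect_true(all(sim$truth$skipping == 0))
})

test_that("read simulator refuses gene models without flanking exons", {
  expect_error(simulate_spliced_reads(
    splicing_sim_config(n_genes = 1, exons_per_gene = 2, seed = 1)),
    "flanking")
})

test_that("PPI simulator plants the downstream label structure", {
  cfg <- network_sim_config(n_nodes = 300, edge_prob = 0.015,
                            p_changed_in = 1, p_changed_out = 0, seed = 8)
  sim <- simulate_ppi(cfg)
  inside <- names(sim$status) %in% sim$downstream
  expect_true(all(sim$status[inside] == "changed"))
  expect_true(all(sim$status[!inside] == "unchanged"))
  expect_setequal(sim$downstream,
                  downstream_nodes(sim$graph, sim$seeds, 2))
})

test_that("annotation simulator covers requested sizes and the universe", {
  cfg <- annotation_sim_config(n_genes = 50, n_terms = 100,
                               genes_per_term_mean = 8, seed = 12)
  ann <- simulate_annotations(cfg)
  expect_length(ann$terms, 100)
  expect_true(all(unlist(ann$terms) %in% ann$universe))
  expect_equal(mean(lengths(ann$terms)), 8, tolerance = 0.15)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(splicing_sim_config(psi = 1.2), "strictly")
  expect_error(splicing_sim_config(
    spiked_exons = data.frame(gene = "G0001", exon = 2, psi_case = 0)),
    "psi_case")
  expect_error(phospho_sim_config(log_noise_sd = 0), "log_noise_sd")
  expect_error(phospho_sim_config(channel_bias = c(1, 1)), "channel_bias")
  expect_error(network_sim_config(edge_prob = 0), "edge_prob")
  expect_error(annotation_sim_config(n_terms = 0), "n_terms")
  expect_error(simulate_ppi(network_sim_config(
    n_nodes = 10, edge_prob = 0.5, seed_kinases = "absent", seed = 1)),
    "absent")
})
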