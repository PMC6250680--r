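make_matrix <- function(intens, groups = c("case", "case", "control", "control"),
                        conf = 0.99, label = TRUE, shared = FALSE) {
  n <- nrow(intens)
  reporter_matrix(
    data.frame(peptide = paste0("pep", seq_len(n)),
               protein = paste0("P", seq_len(n)), site = "S100",
               fragment = 1L, confidence = conf,
               has_itraq_label = label, shared_spectrum = shared),
    intens, groups)
}

test_that("peptide filtering applies the exclusion rules, strictly on confidence", {
  intens <- matrix(100, 4, 4)
  m <- make_matrix(intens)
  m$rows$has_itraq_label[1] <- FALSE
  m$rows$shared_spectrum[2] <- TRUE
  m$rows$confidence[3] <- 0.95   # exactly at threshold: removed (strict >)
  f <- filter_peptides(m, min_intensity = 0)
  expect_identical(f$rows$peptide, "pep4")
  cnt <- attr(f, "filter_counts")
  expect_identical(unname(cnt[c("no_label", "shared_spectrum",
                                "low_confidence", "kept")]),
                   c(1L, 1L, 1L, 1L))

  all_pass <- filter_peptides(make_matrix(intens), min_intensity = 0)
  expect_identical(all_pass$intensities, intens)
})

test_that("low-intensity rows are dropped against the max-channel rule", {
  intens <- rbind(c(1, 1, 1, 1), c(100, 100, 100, 100))
  f <- filter_peptides(make_matrix(intens), min_intensity = 50)
  expect_equal(nrow(f$rows), 1L)
  expect_equal(unname(f$intensities[1, 1]), 100)
})

test_that("channel normalization equalizes totals, preserves structure, idempotent", {
  m <- make_matrix(cbind(c(1, 1), c(2, 2), c(1, 1), c(4, 4)),
                   groups = c("case", "case", "control", "control"))
  nm <- normalize_channels(m)
  expect_equal(unname(colSums(nm$intensities)), rep(4, 4))
  # relative intensities within a channel preserved
  expect_equal(nm$intensities[1, ] / nm$intensities[2, ], rep(1, 4))

  set.seed(2)
  r <- make_matrix(matrix(rexp(40) + 0.1, 10, 4))
  n1 <- normalize_channels(r)
  n2 <- normalize_channels(n1)
  expect_equal(n1$intensities, n2$intensities, tolerance = 1e-12)
  expect_equal(max(abs(colSums(n1$intensities) -
                         mean(colSums(r$intensities)))), 0,
               tolerance = 1e-9)

  zero <- make_matrix(cbind(c(0, 0), c(1, 1), c(1, 1), c(1, 1)))
  expect_error(normalize_channels(zero), "zero total")
})

test_that("geometric-mean quantities and ratios follow forced arithmetic", {
  expect_equal(fragment_site_quantity(c(5, 5, 5)), 5)
  expect_equal(fragment_site_quantity(c(4, 9)), 6)
  expect_equal(fragment_site_quantity(c(2, 4, 8)), 4)
  expect_true(all(sapply(1:10, function(i) {
    x <- rexp(5) + 0.01
    q <- fragment_site_quantity(x)
    q >= min(x) && q <= max(x)
  })))
  expect_error(fragment_site_quantity(c(1, 0)), "positive")

  expect_equal(peptide_ratio(c(2, 2), c(1, 1)), 2)
  expect_equal(peptide_ratio(c(1, 4), c(1, 1)), 2)
  expect_equal(peptide_ratio(c(3, 7), c(3, 7)), 1)

  expect_equal(protein_site_ratio(c(2, 2), c(5, 1)), 2)
  expect_equal(protein_site_ratio(c(1, 4)), 2)
  expect_equal(protein_site_ratio(c(1, 4), c(3, 1)), sqrt(2))
  expect_error(protein_site_ratio(c(1, 2), c(0, 0)), "weights")
})

test_that("ratios are invariant to global intensity rescaling", {
  set.seed(8)
  cfg <- phospho_sim_config(n_proteins = 20, seed = 5)
  m <- simulate_phospho(cfg)
  m2 <- reporter_matrix(m$rows, m$intensities * 37.5, m$groups)
  q1 <- site_channel_quantities(m)
  q2 <- site_channel_quantities(m2)
  expect_equal(q2$quant / q1$quant,
               matrix(37.5, nrow(q1$quant), ncol(q1$quant)),
               ignore_attr = TRUE, tolerance = 1e-12)
  r1 <- site_differential_test(q1)
  r2 <- site_differential_test(q2)
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("identical replicate structure gives p = 1, never significant", {
  q <- list(quant = matrix(c(2, 2, 2, 2, 1, 1, 1, 1), 2, 4, byrow = FALSE,
                           dimnames = list(c("P1 S100", "P2 S100"), NULL)),
            sites = data.frame(protein = c("P1", "P2"),
                               site = c("S100", "S100")),
            groups = c("case", "case", "control", "control"))
  # both sites have identical case and control log ratios -> degenerate
  q$quant <- matrix(1, 2, 4, dimnames = list(c("P1 S100", "P2 S100"), NULL))
  res <- site_differential_test(q, center_ratios = FALSE)
  expect_equal(res$p, c(1, 1))
  expect_false(any(res$significant))
})

test_that("planted differential sites are recovered end to end", {
  spiked <- data.frame(protein = sprintf("P%04d", 1:10), site = "S100",
                       delta = 2)
  cfg <- phospho_sim_config(n_proteins = 200, peptides_per_protein = 1,
                            fragments_per_peptide = 3, log_noise_sd = 0.1,
                            spiked_sites = spiked, seed = 77)
  res <- quantify_sites(simulate_phospho(cfg))
  hit <- res$protein %in% spiked$protein
  expect_gte(sum(res$significant[hit]), 9)
  expect_lte(mean(res$significant[!hit]), 0.05)
  expect_lt(abs(mean(res$log2_ratio[hit]) - 2), 0.1)
})

test_that("null configuration keeps the site false-call rate at bay", {
  cfg <- phospho_sim_config(n_proteins = 400, peptides_per_protein = 1,
                            fragments_per_peptide = 2, log_noise_sd = 0.2,
                            seed = 123)
  res <- quantify_sites(simulate_phospho(cfg))
  # p should be roughly uniform; q < 0.05 calls at most sporadic
  expect_lte(mean(res$significant), 0.01)
  expect_gt(mean(res$p), 0.4)
})
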