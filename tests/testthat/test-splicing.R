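model3 <- data.frame(gene = "G1", exon = 1:3,
                     start = c(0L, 200L, 400L), end = c(100L, 300L, 500L))

test_that("inclusion and skipping reads are counted by the boundary rules", {
  aln <- c("50-100,400-450",   # junction (100,400): skip of exon 2
           "220-280")          # block inside exon 2: inclusion
  expect_identical(count_inclusion_skipping(model3, aln, 2),
                   c(inclusion = 1L, skipping = 1L))
  expect_identical(count_inclusion_skipping(model3, character(0), 2),
                   c(inclusion = 0L, skipping = 0L))
  # acceptor boundary off by one: no skip under the exact rule ...
  off <- "50-100,399-450"
  expect_identical(count_inclusion_skipping(model3, off, 2)[["skipping"]], 0L)
  # ... but accepted under a +/-1 bp tolerance
  expect_identical(
    count_inclusion_skipping(model3, off, 2, tolerance = 1)[["skipping"]], 1L)
  expect_error(count_inclusion_skipping(model3, aln, 1), "internal")
  expect_error(count_inclusion_skipping(model3, aln, 3), "internal")
})

test_that("a read counts at most once per category", {
  # two blocks both overlapping exon 2
  aln <- "210-230,250-270"
  expect_identical(count_inclusion_skipping(model3, aln, 2)[["inclusion"]], 1L)
})

test_that("adjusted log2 ratio follows its definition and sign convention", {
  expect_equal(adjusted_log2_ratio(10, 10, 5, 10), 1)
  expect_equal(adjusted_log2_ratio(3, 7, 3, 7), 0)
  expect_equal(adjusted_log2_ratio(1, 8, 1, 2), -2)
  expect_true(is.na(adjusted_log2_ratio(0, 10, 5, 10)))
  expect_error(adjusted_log2_ratio(-1, 1, 1, 1), "non-negative")
  # antisymmetry under swapping case and control
  set.seed(3)
  for (i in 1:20) {
    x <- rpois(4, 20) + 1
    expect_equal(adjusted_log2_ratio(x[1], x[2], x[3], x[4]),
                 -adjusted_log2_ratio(x[3], x[4], x[1], x[2]),
                 tolerance = 1e-12)
  }
})

test_that("the positive-integer rule gates exon testing", {
  r <- test_exon(0, 50, 5, 45)
  expect_false(r$tested)
  expect_true(is.na(r$p))
  expect_equal(test_exon(1, 1, 1, 1)$p, 1)
  expect_equal(test_exon(10, 1, 1, 10)$p, 244 / 705432, tolerance = 1e-10)
  expect_error(test_exon(-1, 1, 1, 1), "non-negative")
})

test_that("significance calling adjusts across tested exons only", {
  res <- data.frame(gene = c("G1", "G1", "G2"), exon = c(2, 3, 2),
                    adjusted_log2 = c(1, NA, 0),
                    p = c(0.04, NA, 1), tested = c(TRUE, FALSE, TRUE))
  out <- call_significant(res)
  expect_equal(out$q[out$gene == "G1" & out$exon == 2], 0.08)
  expect_true(is.na(out$q[!out$tested]))
  expect_false(any(out$significant[!out$tested]))

  single <- call_significant(data.frame(gene = "G1", exon = 2,
                                        adjusted_log2 = 1, p = 0.04,
                                        tested = TRUE))
  expect_true(single$significant)
  expect_equal(single$q, 0.04)
})

test_that("RPKM follows its definition", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 500, 2e6), 0)
  expect_equal(rpkm(100, 500, 2e6), 100)
  expect_error(rpkm(10, 0, 1e6), "positive")
})

test_that("splicing_analysis sums replicates and is two-sided in groups", {
  cfg <- splicing_sim_config(
    n_genes = 30, exons_per_gene = 4, depth = 100, psi = 0.7,
    spiked_exons = data.frame(gene = c("G0001", "G0002"), exon = 2,
                              psi_case = c(0.2, 0.95)),
    replicates_per_group = 3, seed = 21)
  d <- simulate_splicing_counts(cfg)
  res <- splicing_analysis(d)
  expect_true(res$significant[res$gene == "G0001" & res$exon == 2])
  # swapping the group labels flips the sign but keeps p
  d2 <- d; d2$group <- ifelse(d$group == "case", "control", "case")
  res2 <- splicing_analysis(d2)
  key <- paste(res$gene, res$exon)
  key2 <- paste(res2$gene, res2$exon)
  res2 <- res2[match(key, key2), ]
  expect_equal(res$p, res2$p, tolerance = 1e-12)
  expect_equal(res$adjusted_log2, -res2$adjusted_log2, tolerance = 1e-12)
})

test_that("overlap and recovery scoring combine comparisons correctly", {
  mk <- function(sig, l2 = 2) {
    data.frame(gene = c("G1", "G1", "G2", "G3"), exon = c(2, 3, 2, 2),
               adjusted_log2 = l2, p = 0.001, tested = TRUE,
               q = ifelse(sig, 0.001, 0.5), significant = sig)
  }
  a <- mk(c(TRUE, TRUE, TRUE, FALSE))
  b <- mk(c(TRUE, FALSE, TRUE, TRUE))
  ov <- overlap_significant(a, b)
  expect_equal(ov$n_exons, 2)
  expect_equal(ov$n_genes, 2)

  disjoint <- overlap_significant(mk(c(TRUE, FALSE, FALSE, FALSE)),
                                  mk(c(FALSE, TRUE, FALSE, FALSE)))
  expect_equal(disjoint$n_exons, 0)
  expect_equal(disjoint$n_genes, 0)

  # treated identical to control: everything recovers
  treated_null <- mk(c(FALSE, FALSE, FALSE, FALSE))
  rec <- recovery_analysis(a, treated_null, ov$exons)
  expect_equal(rec$fraction, 1)
  # treated identical to disease: nothing recovers
  rec2 <- recovery_analysis(a, a, ov$exons)
  expect_equal(rec2$fraction, 0)
  # empty shared set: undefined sentinel
  rec3 <- recovery_analysis(a, a, ov$exons[0, ])
  expect_true(is.na(rec3$fraction))
})

test_that("identical significant sets report their full exon and gene counts", {
  res <- data.frame(gene = rep(c("Ga", "Gb", "Gc"), c(2, 2, 1)),
                    exon = c(2, 3, 2, 3, 2), adjusted_log2 = 1,
                    p = 1e-4, tested = TRUE, q = 1e-3, significant = TRUE)
  ov <- overlap_significant(res, res)
  expect_equal(ov$n_exons, 5)
  expect_equal(ov$n_genes, 3)
})
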