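seg4 <- function(start, end, state, chrom = "chr1")
  bed_intervals(chrom, start, end, payload = state)

test_that("binning assigns whole-bin states and majority on straddles", {
  tr <- bin_segmentation(seg4(0, 600, "E1"))
  expect_equal(tr$bin, 0:2)
  expect_equal(tr$state, rep("E1", 3))

  # 0-300 E1 / 300-600 E2: bin 1 is a 100/100 tie, leftmost state wins
  tr <- bin_segmentation(seg4(c(0, 300), c(300, 600), c("E1", "E2")))
  expect_equal(tr$state[tr$bin == 1], "E1")
  expect_equal(tr$state[tr$bin == 2], "E2")

  # clear majority
  tr <- bin_segmentation(seg4(c(0, 250), c(250, 600), c("E1", "E2")))
  expect_equal(tr$state[tr$bin == 1], "E2")

  expect_equal(nrow(bin_segmentation(
    bed_intervals(character(0), numeric(0), numeric(0),
                  payload = character(0)))), 0L)
  expect_error(bin_segmentation(seg4(c(0, 100), c(300, 400),
                                     c("E1", "E2"))),
               "overlapping segmentation")
})

test_that("binning matches the per-base majority oracle", {
  for (seed in 1:6) {
    seg <- random_segmentation(4000, 3, seed)
    tr <- bin_segmentation(seg, 200)
    om <- oracle_bin_map(seg, 200)
    got <- setNames(tr$state, paste(tr$chrom, tr$bin))
    expect_equal(got[sort(names(got))], om[sort(names(om))])
  }
})

test_that("joint occupancy counts co-covered bins and excludes the rest", {
  n <- binned_track("chr1", 1:10, rep(c("E1", "E2"), each = 5))
  t1 <- binned_track("chr1", 1:10,
                     c("E1", "E1", "E1", "E1", "E2",
                       "E1", "E2", "E2", "E2", "E2"))
  te <- joint_occupancy(n, t1)
  expect_equal(te$observed["E1", "E1"], 4)
  expect_equal(te$observed["E1", "E2"], 1)
  expect_equal(te$observed["E2", "E1"], 1)
  expect_equal(te$observed["E2", "E2"], 4)

  ident <- joint_occupancy(n, n)
  expect_equal(sum(ident$observed) - sum(diag(ident$observed)), 0)

  disj <- joint_occupancy(n, binned_track("chr1", 11:20, rep("E1", 10)))
  expect_equal(disj$total_bins, 0)
  expect_equal(disj$n_excluded, 20)

  expect_error(joint_occupancy(n, binned_track("chr1", 1, "E1",
                                               bin_size = 100)),
               "bin_size")
})

test_that("raw enrichment follows the independence null", {
  n <- binned_track("chr1", 1:10, rep(c("E1", "E2"), each = 5))
  t1 <- binned_track("chr1", 1:10,
                     c("E1", "E1", "E1", "E1", "E2",
                       "E1", "E2", "E2", "E2", "E2"))
  te <- raw_enrichment(joint_occupancy(n, t1))
  expect_equal(te$expected["E1", "E1"], 2.5)
  expect_equal(te$res["E1", "E1"], 1.6)
  # marginals preserved
  expect_equal(rowSums(te$expected), rowSums(te$observed))
  expect_equal(colSums(te$expected), colSums(te$observed))

  ident <- raw_enrichment(joint_occupancy(n, n))
  expect_equal(diag(ident$res), c(E1 = 2, E2 = 2))
  expect_equal(ident$res["E1", "E2"], 0)

  mono <- binned_track("chr1", 1:8, rep("E1", 8))
  expect_equal(raw_enrichment(joint_occupancy(mono, mono))$res["E1", "E1"],
               1.0)
  expect_error(raw_enrichment(joint_occupancy(
    mono, binned_track("chr2", 1, "E1"))), "total_bins")
})

test_that("normalized enrichment is the ratio of opposite transitions", {
  n <- binned_track("chr1", 1:10, rep(c("E1", "E2"), c(6, 4)))
  t1 <- binned_track("chr1", 1:10,
                     c(rep("E1", 4), "E2", "E2", "E1", rep("E2", 3)))
  te <- normalized_enrichment(raw_enrichment(joint_occupancy(n, t1)))
  expect_equal(te$res["E1", "E2"], 2 / (6 * 5 / 10))
  expect_equal(te$res["E2", "E1"], 1 / (4 * 5 / 10))
  expect_equal(te$nes["E1", "E2"], (2 / 3) / 0.5)
  expect_equal(te$nes["E1", "E2"] * te$nes["E2", "E1"], 1)

  # symmetric swap counts give nes 1 both ways
  n2 <- binned_track("chr1", 1:4, c("E1", "E1", "E2", "E2"))
  t2 <- binned_track("chr1", 1:4, c("E1", "E2", "E1", "E2"))
  te2 <- normalized_enrichment(raw_enrichment(joint_occupancy(n2, t2)))
  expect_equal(te2$nes["E1", "E2"], 1)
  expect_equal(te2$nes["E2", "E1"], 1)

  # zero reverse enrichment flags the entry rather than returning Inf
  n3 <- binned_track("chr1", 1:10, rep(c("E1", "E2"), c(5, 5)))
  t3 <- binned_track("chr1", 1:10,
                     c(rep("E1", 3), "E2", "E2", rep("E2", 5)))
  te3 <- normalized_enrichment(raw_enrichment(joint_occupancy(n3, t3)))
  expect_equal(te3$res["E2", "E1"], 0)
  expect_true(is.na(te3$nes["E1", "E2"]))
  expect_false(any(is.infinite(te3$nes), na.rm = TRUE))
})

test_that("state independence is tested by Pearson chi-square", {
  te <- list(observed = matrix(c(5, 0, 0, 5), 2, 2), total_bins = 10)
  class(te) <- "transition_enrichment"
  got <- chisq_independence(te)
  expect_equal(got$statistic, 10.0)
  expect_equal(got$df, 1)

  te$observed <- matrix(c(2, 3, 2, 3), 2, 2)
  got <- chisq_independence(te)
  expect_equal(got$statistic, 0)
  expect_equal(got$p, 1)

  te$observed <- matrix(c(3, 4), 1, 2)
  expect_error(chisq_independence(te), "degenerate")
})

test_that("transition loci map to promoter genes, direction-sensitive", {
  genes <- normalize_gene_models(data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1", strand = "+",
    tx_start = c(1000, 1400), tx_end = c(8000, 9000),
    exon_starts = c("1000", "1400"), exon_ends = c("8000", "9000"),
    stringsAsFactors = FALSE))
  # bin 5 ([1000,1200)) lies in both promoters (gA tss 1000, gB tss 1400)
  n <- binned_track("chr1", 0:9, c(rep("E1", 5), "E4", rep("E1", 4)))
  t1 <- binned_track("chr1", 0:9, rep("E1", 10))
  expect_equal(transition_genes(n, t1, "E4", "E1", genes), c("gA", "gB"))
  expect_equal(transition_genes(n, t1, "E1", "E4", genes), character(0))
  expect_error(transition_genes(n, t1, "E9", "E1", genes),
               "unknown state label")
})

test_that("the 19-state preset carries the functional group annotation", {
  st <- chromhmm19_states()
  expect_equal(nrow(st), 19L)
  expect_equal(st$group[c(1, 5, 9, 15, 16, 17, 18, 19)],
               c("promoter", "transcribed", "enhancer", "znf",
                 "bivalent_tss", "bivalent_weak_enhancer", "polycomb",
                 "quiescent"))
})
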