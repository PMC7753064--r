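simple_genes <- function(n = 3, spacing = 20000) {
  normalize_gene_models(data.frame(
    gene_id = sprintf("g%02d", seq_len(n)), chrom = "chr1", strand = "+",
    tx_start = spacing * seq_len(n), tx_end = spacing * seq_len(n) + 8000,
    exon_starts = as.character(spacing * seq_len(n)),
    exon_ends = as.character(spacing * seq_len(n) + 8000),
    stringsAsFactors = FALSE))
}

# paired expression table with prescribed log2 FPKM means
expr_from_log2 <- function(gene_ids, normal_log2, tumor_log2,
                           n_patients = 4) {
  nm <- matrix(rep(normal_log2, n_patients), ncol = n_patients)
  tm <- matrix(rep(tumor_log2, n_patients), ncol = n_patients)
  fpkm <- cbind(2^nm, 2^tm)
  rownames(fpkm) <- gene_ids
  colnames(fpkm) <- c(sprintf("N%d", 1:n_patients),
                      sprintf("T%d", 1:n_patients))
  expression_table(fpkm, data.frame(patient = sprintf("P%d", 1:n_patients),
                                    normal = sprintf("N%d", 1:n_patients),
                                    tumor = sprintf("T%d", 1:n_patients)))
}

test_that("methylation summary tabulates hypo/hyper against CGIs", {
  dmps <- data.frame(
    delta_beta = c(rep(-0.3, 9), 0.4),
    in_cgi = c(rep(FALSE, 8), TRUE, TRUE))
  s <- summarize_methylation(dmps)
  expect_equal(unname(as.vector(t(s$cgi_table))), c(8, 1, 0, 1))
  expect_equal(s$frac_hypo, 0.9)
  expect_equal(s$chisq_yates$statistic, oracle_yates(s$cgi_table))

  allhypo <- summarize_methylation(data.frame(delta_beta = rep(-0.2, 5),
                                              in_cgi = rep(FALSE, 5)))
  expect_true(is.na(allhypo$chisq_yates$statistic))
  expect_equal(allhypo$frac_hypo, 1)

  s0 <- summarize_methylation(data.frame(delta_beta = numeric(0),
                                         in_cgi = logical(0)))
  expect_equal(s0$n_total, 0L)
})

test_that("gene profiles record promoter marks with weighted directions", {
  genes <- simple_genes(1)
  tss <- genes$tss[1]
  alt <- data.frame(mark = "H3K4me3", chrom = "chr1",
                    start = tss - 500, end = tss + 500,
                    direction = "up", stat = 1.2)
  pr <- build_gene_profiles(alt, NULL, genes)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$direction, "up")

  # histone mark + hypo DMPs: two marks, mC direction from DMP signs
  dmps <- data.frame(chrom = "chr1", pos = tss + c(-100, 0, 100),
                     delta_beta = c(-0.3, -0.2, -0.4))
  alt2 <- data.frame(mark = "H3K27ac", chrom = "chr1",
                     start = tss - 500, end = tss + 500,
                     direction = "up", stat = 1.0)
  pr2 <- build_gene_profiles(alt2, dmps, genes)
  expect_setequal(pr2$mark, c("H3K27ac", "mC"))
  expect_equal(pr2$direction[pr2$mark == "mC"], "down")
  ps <- profile_summary(pr2)
  expect_equal(ps$n_marks, 2L)
  expect_equal(ps$subgroup, "active")

  # equal-bp conflicting directions drop the mark with a warning
  alt3 <- data.frame(mark = "H3K4me1", chrom = "chr1",
                     start = c(tss - 400, tss + 100),
                     end = c(tss - 100, tss + 400),
                     direction = c("up", "down"), stat = c(1, -1))
  expect_warning(pr3 <- build_gene_profiles(alt3, NULL, genes),
                 "tied directions")
  expect_equal(nrow(pr3), 0L)

  expect_error(build_gene_profiles(
    data.frame(mark = "H3K9me3", chrom = "chr1", start = 1, end = 2,
               direction = "up", stat = 1), NULL, genes),
    "unknown mark")
})

test_that("subgroup classification follows the voting rule", {
  expect_equal(classify_subgroup(c("H3K4me3", "mC"), c("up", "down")),
               "active")
  expect_equal(classify_subgroup(c("H3K4me1", "H3K27me3"),
                                 c("down", "up")),
               "repressive")
  expect_equal(classify_subgroup(c("H3K27ac", "H3K27me3"), c("up", "up")),
               "poised")
  expect_error(classify_subgroup(character(0), character(0)),
               "empty profile")
})

test_that("additive effect reports per-cell fold change and paired t", {
  genes <- simple_genes(2)
  tsss <- genes$tss
  alt <- data.frame(mark = "H3K4me3", chrom = "chr1",
                    start = tsss - 200, end = tsss + 200,
                    direction = "up", stat = 1)
  pr <- build_gene_profiles(alt, NULL, genes)

  # per-patient mean log2 differences 1, 2, 3 -> t = mean/(sd/sqrt(n))
  fpkm <- rbind(g01 = 2^c(3, 3, 3, 4, 5, 6),
                g02 = 2^c(5, 5, 5, 6, 7, 8))
  colnames(fpkm) <- c("N1", "N2", "N3", "T1", "T2", "T3")
  expr <- expression_table(fpkm,
                           data.frame(patient = c("P1", "P2", "P3"),
                                      normal = c("N1", "N2", "N3"),
                                      tumor = c("T1", "T2", "T3")))
  ae <- additive_effect(pr, expr)
  row <- ae[ae$group == "1" & ae$subgroup == "active", ]
  expect_equal(row$n_genes, 2L)
  expect_equal(row$paired_t, 2 / (1 / sqrt(3)), tolerance = 1e-3)

  # tumor == normal: zero fold change, t suppressed
  same <- expr_from_log2(genes$gene_id, c(3, 5), c(3, 5))
  ae0 <- additive_effect(pr, same)
  row0 <- ae0[ae0$group == "1" & ae0$subgroup == "active", ]
  expect_equal(row0$mean_log2fc, 0, tolerance = 1e-9)
  expect_true(is.na(row0$paired_t))

  # group sizes conserve profiled genes
  expect_equal(sum(ae$n_genes), nrow(profile_summary(pr)))
  expect_error(additive_effect(pr, expr_from_log2("gX", 1, 1)),
               "absent from expression")
})

test_that("candidate retention needs subgroup, fold change and p", {
  genes <- simple_genes(3)
  tsss <- genes$tss
  alt <- data.frame(
    mark = c("H3K4me3", "H3K4me3", "H3K27ac", "H3K27me3"),
    chrom = "chr1",
    start = c(tsss - 200, tsss[3] - 600),
    end = c(tsss + 200, tsss[3] - 300),
    direction = c("up", "up", "up", "up"), stat = 1)
  pr <- build_gene_profiles(alt, NULL, genes)
  ps <- profile_summary(pr)
  expect_equal(ps$subgroup[ps$gene_id == "g03"], "poised")

  # g01 active fc 1.5, g02 active fc 0.9, g03 poised fc 2
  expr <- expr_from_log2(genes$gene_id, c(3, 3, 3), c(4.5, 3.9, 5))
  # add tiny patient jitter so the paired t is defined
  set.seed(1)
  expr$fpkm <- expr$fpkm * 2^matrix(rnorm(length(expr$fpkm), 0, 0.01),
                                    nrow = 3)
  cand <- select_candidates(pr, expr)
  expect_equal(cand$overexpressed, "g01")
  expect_equal(cand$underexpressed, character(0))

  two_pair <- expression_table(
    expr$fpkm[, c("N1", "N2", "T1", "T2")],
    data.frame(patient = c("P1", "P2"), normal = c("N1", "N2"),
               tumor = c("T1", "T2")))
  expect_error(select_candidates(pr, two_pair), "insufficient pairing")
})

test_that("promoter methylation anticorrelates with expression when planted", {
  genes <- simple_genes(30, spacing = 10000)
  set.seed(3)
  fc <- rnorm(30, 0, 1)
  dmps <- data.frame(chrom = "chr1", pos = genes$tss,
                     delta_beta = pmax(-1, pmin(1, -fc / 4)))
  expr <- expr_from_log2(genes$gene_id, rep(3, 30), 3 + fc)
  mec <- methylation_expression_correlation(dmps, expr, genes)
  expect_equal(mec$r_overall, -1, tolerance = 1e-3)
  expect_equal(mec$fraction_negative, 1)

  # independent draws: no systematic correlation
  dmps2 <- data.frame(chrom = "chr1", pos = genes$tss,
                      delta_beta = rnorm(30, 0, 0.2))
  mec2 <- methylation_expression_correlation(dmps2, expr, genes)
  expect_lt(abs(mec2$r_overall), 0.5)
})

test_that("stratified Spearman hits the monotone extremes", {
  genes <- simple_genes(12, spacing = 10000)
  tsss <- genes$tss
  stat <- seq(0.1, 1.2, by = 0.1)
  alt <- data.frame(mark = "H3K27ac", chrom = "chr1", start = tsss - 200,
                    end = tsss + 200, direction = "up", stat = stat)
  pr <- build_gene_profiles(alt, NULL, genes)
  expr_up <- expr_from_log2(genes$gene_id, rep(3, 12), 3 + stat)
  ss <- stratified_spearman(pr, expr_up)
  expect_equal(ss$rho[ss$mark == "H3K27ac" & ss$stratum == "1 mark"], 1)
  expr_dn <- expr_from_log2(genes$gene_id, rep(3, 12), 3 - stat)
  ss2 <- stratified_spearman(pr, expr_dn)
  expect_equal(ss2$rho[ss2$mark == "H3K27ac" & ss2$stratum == "1 mark"],
               -1)
  # >1-mark stratum empty here: suppressed
  expect_true(is.na(ss$rho[ss$stratum == ">1 mark"]))
})

test_that("pairwise mark correlation is computed on shared genes, masked", {
  genes <- simple_genes(20, spacing = 10000)
  tsss <- genes$tss
  set.seed(4)
  sa <- rnorm(20)
  alt <- rbind(
    data.frame(mark = "H3K4me3", chrom = "chr1", start = tsss - 300,
               end = tsss + 300, direction = ifelse(sa > 0, "up", "down"),
               stat = sa),
    data.frame(mark = "H3K27ac", chrom = "chr1", start = tsss - 200,
               end = tsss + 200, direction = ifelse(sa > 0, "up", "down"),
               stat = 2 * sa))
  pm <- pairwise_mark_correlation(alt, "promoter", genes)
  expect_equal(pm$r["H3K4me3", "H3K27ac"], 1, tolerance = 1e-9)
  expect_equal(pm$n["H3K4me3", "H3K27ac"], 20)

  alt$stat[alt$mark == "H3K27ac"] <- rnorm(20)
  pm2 <- pairwise_mark_correlation(alt, "promoter", genes)
  if (pm2$p["H3K4me3", "H3K27ac"] >= 0.05)
    expect_true(is.na(pm2$r["H3K4me3", "H3K27ac"]))
})

test_that("CDS regions are exons minus UTRs", {
  g <- normalize_gene_models(data.frame(
    gene_id = "gA", chrom = "chr1", strand = "+", tx_start = 0,
    tx_end = 1000, exon_starts = "0,600", exon_ends = "400,1000",
    utr5_start = 0, utr5_end = 100, utr3_start = 900, utr3_end = 1000,
    stringsAsFactors = FALSE))
  cds <- cds_regions(g)
  expect_equal(cds$start, c(100, 600))
  expect_equal(cds$end, c(400, 900))
})
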