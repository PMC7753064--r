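.marks6 <- c("H3K4me1", "H3K4me3", "H3K27ac", "H3K27me3", "H3K36me3", "mC")
.active_marks <- c("H3K4me1", "H3K4me3", "H3K27ac", "H3K36me3")
.repressive_marks <- c("H3K27me3", "mC")

#' The six-mark vocabulary
#' @return character vector of the mark names handled by the integration
#'   stage: five core histone modifications plus DNA methylation (\code{mC}).
#' @export
epi_marks <- function() .marks6

.log2fc_eps <- 0.01

#' Summarize differentially methylated positions
#'
#' Tabulates hypo- (\code{delta_beta < 0}) vs hypermethylated
#' (\code{delta_beta > 0}) positions against CpG-island membership and runs
#' the Yates-corrected chi-square test of association,
#' \code{sum((|o - e| - 0.5)^2 / e)}. Positions with \code{delta_beta == 0}
#' are counted separately and excluded from the table.
#'
#' @param dmps data.frame with columns \code{delta_beta} and \code{in_cgi}
#'   (logical).
#' @return list with \code{n_total}, \code{n_hypo}, \code{n_hyper},
#'   \code{n_zero}, \code{frac_hypo}, \code{cgi_table} (rows hypo/hyper,
#'   cols non-CGI/CGI) and \code{chisq_yates} (\code{statistic}, \code{p};
#'   \code{NA} when the table is degenerate).
#' @export
summarize_methylation <- function(dmps) {
  if (nrow(dmps) == 0L)
    return(list(n_total = 0L, n_hypo = 0L, n_hyper = 0L, n_zero = 0L,
                frac_hypo = NA_real_, cgi_table = NULL,
                chisq_yates = list(statistic = NA_real_, p = NA_real_)))
  stopifnot(all(abs(dmps$delta_beta) <= 1))
  hypo <- dmps$delta_beta < 0; hyper <- dmps$delta_beta > 0
  tab <- matrix(c(sum(hypo & !dmps$in_cgi), sum(hypo & dmps$in_cgi),
                  sum(hyper & !dmps$in_cgi), sum(hyper & dmps$in_cgi)),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("hypo", "hyper"), c("non_cgi", "cgi")))
  chis <- list(statistic = NA_real_, p = NA_real_)
  if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    ht <- suppressWarnings(chisq.test(tab, correct = TRUE))
    chis <- list(statistic = unname(ht$statistic), p = ht$p.value)
  }
  list(n_total = nrow(dmps), n_hypo = sum(hypo), n_hyper = sum(hyper),
       n_zero = sum(!hypo & !hyper),
       frac_hypo = sum(hypo) / max(1L, sum(hypo) + sum(hyper)),
       cgi_table = tab, chisq_yates = chis)
}

#' Build per-gene epigenetic profiles from promoter overlaps
#'
#' For each gene, a mark enters the profile if at least one of its altered
#' regions (or, for \code{mC}, at least one differentially methylated
#' position) overlaps the promoter window (\code{tss +/- flank}). The
#' direction per gene-mark is the sign of the bp-weighted sum of signed
#' overlaps for region marks, and the majority sign of promoter DMPs for
#' \code{mC}; exact ties drop the mark with a warning. A bp-weighted (or
#' DMP-mean) effect size is carried along for the correlation analyses.
#'
#' @param alterations data.frame of differential mark regions with columns
#'   \code{mark}, \code{chrom}, \code{start}, \code{end}, \code{direction}
#'   (\code{"up"}/\code{"down"}) and \code{stat} (signed effect size).
#' @param dmps data.frame of methylated positions with columns \code{chrom},
#'   \code{pos} (0-based) and \code{delta_beta}; may be \code{NULL}.
#' @param genes gene-model data.frame.
#' @param flank promoter half-width (default 2000).
#' @return a \code{gene_epi_profiles} data.frame in long form: one row per
#'   (gene_id, mark) with \code{direction} and \code{stat}.
#' @export
build_gene_profiles <- function(alterations, dmps, genes, flank = 2000) {
  if (!is.null(alterations) && nrow(alterations)) {
    bad <- setdiff(unique(alterations$mark), .marks6)
    if (length(bad))
      stop("unknown mark name(s): ", paste(bad, collapse = ", "),
           "; expected one of ", paste(.marks6, collapse = ", "))
  }
  prom <- promoters_of(genes, flank)
  gp <- as_gr(prom)
  rows <- list()
  if (!is.null(alterations) && nrow(alterations)) {
    ga <- as_gr(alterations)
    hits <- GenomicRanges::findOverlaps(gp, ga, ignore.strand = TRUE)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      ov_bp <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(gp)[qi], GenomicRanges::ranges(ga)[si]))
      sgn <- ifelse(alterations$direction[si] == "up", 1, -1)
      dt <- data.table::data.table(
        gene_id = prom$payload[qi], mark = alterations$mark[si],
        w = ov_bp, s = sgn, stat = alterations$stat[si])
      w <- s <- stat <- NULL  # data.table NSE
      agg <- dt[, list(score = sum(w * s), stat = sum(w * stat) / sum(w)),
                by = c("gene_id", "mark")]
      rows <- c(rows, list(as.data.frame(agg)))
    }
  }
  if (!is.null(dmps) && nrow(dmps)) {
    gd <- as_gr(data.frame(chrom = dmps$chrom, start = dmps$pos,
                           end = dmps$pos + 1))
    hits <- GenomicRanges::findOverlaps(gp, gd, ignore.strand = TRUE)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      dt <- data.table::data.table(gene_id = prom$payload[qi],
                                   db = dmps$delta_beta[si])
      db <- NULL
      agg <- dt[, list(score = sum(sign(db)), stat = mean(db)),
                by = "gene_id"]
      agg$mark <- "mC"
      rows <- c(rows, list(as.data.frame(agg)[, c("gene_id", "mark",
                                                  "score", "stat")]))
    }
  }
  if (!length(rows)) {
    out <- data.frame(gene_id = character(), mark = character(),
                      direction = character(), stat = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("gene_epi_profiles", "data.frame")
    return(out)
  }
  all <- do.call(rbind, rows)
  tie <- all$score == 0
  if (any(tie))
    warning(sum(tie), " gene-mark pair(s) dropped for tied directions: ",
            paste(head(paste0(all$gene_id[tie], "/", all$mark[tie]), 5L),
                  collapse = ", "))
  all <- all[!tie, , drop = FALSE]
  out <- data.frame(gene_id = all$gene_id, mark = all$mark,
                    direction = ifelse(all$score > 0, "up", "down"),
                    stat = all$stat, stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$mark), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_epi_profiles", "data.frame")
  out
}

#' Classify a gene's mark profile as active, poised or repressive
#'
#' H3K4me1, H3K4me3, H3K27ac and H3K36me3 are active signals; H3K27me3 and
#' DNA methylation (\code{mC}) are repressive. Each (mark, direction) entry
#' votes "activating" (active mark up, or repressive mark down) or
#' "silencing" (active mark down, or repressive mark up). All votes
#' activating gives \code{"active"}, all silencing \code{"repressive"},
#' and any conflict \code{"poised"}.
#'
#' @param marks character vector of mark names (at least one).
#' @param directions matching vector of \code{"up"}/\code{"down"}.
#' @return one of \code{"active"}, \code{"poised"}, \code{"repressive"}.
#' @export
classify_subgroup <- function(marks, directions) {
  if (length(marks) == 0L) stop("empty profile: no altered marks")
  stopifnot(length(marks) == length(directions),
            all(marks %in% .marks6), all(directions %in% c("up", "down")))
  activating <- (marks %in% .active_marks & directions == "up") |
    (marks %in% .repressive_marks & directions == "down")
  if (all(activating)) "active"
  else if (all(!activating)) "repressive"
  else "poised"
}

#' Per-gene summary of an epigenetic profile table
#'
#' Collapses a long \code{gene_epi_profiles} table to one row per gene with
#' the distinct-mark count and the active/poised/repressive subgroup.
#'
#' @param profiles \code{gene_epi_profiles} data.frame.
#' @return data.frame with \code{gene_id}, \code{n_marks}, \code{subgroup},
#'   \code{group} (\code{"1"}, \code{"2"}, \code{"3"}, \code{"4+"}).
#' @export
profile_summary <- function(profiles) {
  if (nrow(profiles) == 0L)
    return(data.frame(gene_id = character(), n_marks = integer(),
                      subgroup = character(), group = character(),
                      stringsAsFactors = FALSE))
  sp <- split(profiles, profiles$gene_id)
  data.frame(
    gene_id = names(sp),
    n_marks = vapply(sp, nrow, 0L),
    subgroup = vapply(sp, function(d)
      classify_subgroup(d$mark, d$direction), ""),
    group = vapply(sp, function(d)
      if (nrow(d) >= 4L) "4+" else as.character(nrow(d)), ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

## per-gene log2 fold change of mean FPKM, tumor vs normal
gene_log2fc <- function(expr, eps = .log2fc_eps) {
  tm <- rowMeans(expr$fpkm[, expr$pairing$tumor, drop = FALSE])
  nm <- rowMeans(expr$fpkm[, expr$pairing$normal, drop = FALSE])
  log2((tm + eps) / (nm + eps))
}

#' Additive effect of mark combinations on expression
#'
#' Groups profiled genes by the number of altered promoter marks (1, 2, 3,
#' 4+) and subgroup (active/poised/repressive) and reports the mean per-gene
#' log2 FPKM fold change (tumor vs normal, pseudocount 0.01) per cell,
#' together with a paired t-test comparing the per-patient mean log2
#' expression of the cell's genes between tumor and normal samples.
#' Cells with fewer than two genes report their count but suppress the
#' statistics.
#'
#' @param profiles \code{gene_epi_profiles} data.frame.
#' @param expr \code{expression_table}; every profiled gene must be present.
#' @return data.frame with \code{group}, \code{subgroup}, \code{n_genes},
#'   \code{mean_log2fc}, \code{se_log2fc}, \code{paired_t}, \code{p}.
#' @export
additive_effect <- function(profiles, expr) {
  ps <- profile_summary(profiles)
  miss <- setdiff(ps$gene_id, rownames(expr$fpkm))
  if (length(miss))
    stop("profiled gene(s) absent from expression table: ",
         paste(head(miss, 5L), collapse = ", "))
  fc <- gene_log2fc(expr)
  lt <- log2(expr$fpkm[, expr$pairing$tumor, drop = FALSE] + .log2fc_eps)
  ln <- log2(expr$fpkm[, expr$pairing$normal, drop = FALSE] + .log2fc_eps)
  cells <- expand.grid(group = c("1", "2", "3", "4+"),
                       subgroup = c("active", "poised", "repressive"),
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    g <- ps$gene_id[ps$group == cells$group[i] &
                      ps$subgroup == cells$subgroup[i]]
    n <- length(g)
    if (n < 2L)
      return(data.frame(cells[i, ], n_genes = n, mean_log2fc = NA_real_,
                        se_log2fc = NA_real_, paired_t = NA_real_,
                        p = NA_real_))
    v <- fc[g]
    tt <- tryCatch({
      h <- t.test(colMeans(lt[g, , drop = FALSE]),
                  colMeans(ln[g, , drop = FALSE]), paired = TRUE)
      c(unname(h$statistic), h$p.value)
    }, error = function(e) c(NA_real_, NA_real_))
    data.frame(cells[i, ], n_genes = n, mean_log2fc = mean(v),
               se_log2fc = sd(v) / sqrt(n), paired_t = tt[1L], p = tt[2L])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## per-gene paired t-test on log2(FPKM + eps) across patients
.per_gene_paired_t <- function(expr, gene_ids) {
  if (nrow(expr$pairing) < 3L) stop("insufficient pairing for t-test")
  lt <- log2(expr$fpkm[gene_ids, expr$pairing$tumor, drop = FALSE] +
               .log2fc_eps)
  ln <- log2(expr$fpkm[gene_ids, expr$pairing$normal, drop = FALSE] +
               .log2fc_eps)
  vapply(seq_along(gene_ids), function(i) {
    tryCatch(t.test(lt[i, ], ln[i, ], paired = TRUE)$p.value,
             error = function(e) NA_real_)
  }, 0)
}

#' Select over- and underexpressed candidate genes
#'
#' Retains active-subgroup genes with log2 FPKM fold change above
#' \code{fc_threshold} (overexpressed) and repressive-subgroup genes below
#' \code{-fc_threshold} (underexpressed), each additionally requiring a
#' per-gene paired t-test p-value (tumor vs normal log2 FPKM across
#' patients) below \code{p_threshold}. Raw p gates retention; BH-adjusted q
#' is reported alongside.
#'
#' @param profiles \code{gene_epi_profiles} data.frame.
#' @param expr \code{expression_table} with at least 3 patient pairs.
#' @param fc_threshold absolute log2 fold-change cutoff (default 1).
#' @param p_threshold raw p cutoff (default 0.05).
#' @return list with \code{overexpressed}, \code{underexpressed} (character
#'   vectors) and \code{table} (gene_id, subgroup, log2fc, p, q).
#' @export
select_candidates <- function(profiles, expr, fc_threshold = 1.0,
                              p_threshold = 0.05) {
  ps <- profile_summary(profiles)
  ps <- ps[ps$gene_id %in% rownames(expr$fpkm), , drop = FALSE]
  if (nrow(ps) == 0L)
    return(list(overexpressed = character(0),
                underexpressed = character(0),
                table = data.frame(gene_id = character(),
                                   subgroup = character(), log2fc = numeric(),
                                   p = numeric(), q = numeric())))
  fc <- gene_log2fc(expr)[ps$gene_id]
  p <- .per_gene_paired_t(expr, ps$gene_id)
  tab <- data.frame(gene_id = ps$gene_id, subgroup = ps$subgroup,
                    log2fc = unname(fc), p = p,
                    q = p.adjust(p, "BH"), stringsAsFactors = FALSE)
  over <- tab$gene_id[tab$subgroup == "active" & tab$log2fc > fc_threshold &
                        !is.na(tab$p) & tab$p < p_threshold]
  under <- tab$gene_id[tab$subgroup == "repressive" &
                         tab$log2fc < -fc_threshold &
                         !is.na(tab$p) & tab$p < p_threshold]
  list(overexpressed = sort(over), underexpressed = sort(under), table = tab)
}

#' Promoter methylation vs expression fold change
#'
#' Correlates, across genes, the mean promoter delta-beta of differentially
#' methylated positions with the expression log2 fold change, and reports
#' the fraction of genes where the two move in opposite directions.
#'
#' @param dmps DMP data.frame (chrom, pos, delta_beta).
#' @param expr \code{expression_table}.
#' @param genes gene-model data.frame.
#' @param flank promoter half-width (default 2000).
#' @return list with \code{per_gene} table (gene_id, mean_delta_beta,
#'   log2fc), \code{fraction_negative}, \code{r_overall}, \code{p} and a
#'   \code{flag} (\code{"ok"} or \code{"zero variance"}).
#' @export
methylation_expression_correlation <- function(dmps, expr, genes,
                                               flank = 2000) {
  prom <- promoters_of(genes, flank)
  gd <- as_gr(data.frame(chrom = dmps$chrom, start = dmps$pos,
                         end = dmps$pos + 1))
  hits <- GenomicRanges::findOverlaps(as_gr(prom), gd, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  mdb <- tapply(dmps$delta_beta[si], prom$payload[qi], mean)
  gene_ids <- intersect(names(mdb), rownames(expr$fpkm))
  if (length(gene_ids) < 3L) stop("need >= 3 genes with promoter DMPs")
  fc <- gene_log2fc(expr)[gene_ids]
  db <- as.vector(mdb[gene_ids])
  per_gene <- data.frame(gene_id = gene_ids, mean_delta_beta = db,
                         log2fc = unname(fc), stringsAsFactors = FALSE)
  if (sd(db) == 0 || sd(fc) == 0)
    return(list(per_gene = per_gene, fraction_negative = NA_real_,
                r_overall = NA_real_, p = NA_real_, flag = "zero variance"))
  ct <- cor.test(db, fc, method = "pearson")
  list(per_gene = per_gene,
       fraction_negative = mean(db * fc < 0),
       r_overall = unname(ct$estimate), p = ct$p.value, flag = "ok")
}

#' Mark-effect vs expression correlation, stratified by mark multiplicity
#'
#' For each mark, Spearman correlation between the per-gene mark effect size
#' and the expression log2 fold change, computed separately for genes whose
#' promoter carries only that mark and genes carrying two or more marks.
#' Strata with fewer than 5 genes suppress rho.
#'
#' @param profiles \code{gene_epi_profiles} data.frame.
#' @param expr \code{expression_table}.
#' @return data.frame (mark, stratum, n, rho, p, coverage); coverage is the
#'   stratum size over the number of profiled genes.
#' @export
stratified_spearman <- function(profiles, expr) {
  ps <- profile_summary(profiles)
  fc <- gene_log2fc(expr)
  n_prof <- nrow(ps)
  out <- list()
  for (mk in unique(profiles$mark)) {
    pm <- profiles[profiles$mark == mk, , drop = FALSE]
    nm <- ps$n_marks[match(pm$gene_id, ps$gene_id)]
    for (stratum in c("1 mark", ">1 mark")) {
      sel <- if (stratum == "1 mark") nm == 1L else nm >= 2L
      g <- pm$gene_id[sel]
      g <- g[g %in% names(fc)]
      n <- length(g)
      if (n >= 5L) {
        ct <- suppressWarnings(
          cor.test(pm$stat[match(g, pm$gene_id)], fc[g],
                   method = "spearman"))
        rho <- unname(ct$estimate); p <- ct$p.value
      } else { rho <- NA_real_; p <- NA_real_ }
      out[[length(out) + 1L]] <- data.frame(
        mark = mk, stratum = stratum, n = n, rho = rho, p = p,
        coverage = n / max(1L, n_prof), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Pairwise correlation of mark effect sizes
#'
#' For each pair of marks, Pearson correlation of the signed per-gene effect
#' sizes over the genes where both marks are altered within the scoped
#' region: the promoter window or the coding sequence (union of exons minus
#' UTRs). Entries with p >= 0.05 are masked \code{NA} in the r matrix.
#'
#' @param alterations differential mark region data.frame (as in
#'   \code{\link{build_gene_profiles}}); \code{mC} rows may be supplied as
#'   width-1 positions with \code{stat} = delta_beta.
#' @param scope \code{"promoter"} or \code{"cds"}.
#' @param genes gene-model data.frame.
#' @param flank promoter half-width (default 2000).
#' @return list of matrices \code{r} (masked), \code{r_raw}, \code{p},
#'   \code{n} (shared gene counts).
#' @export
pairwise_mark_correlation <- function(alterations, scope = c("promoter",
                                                             "cds"),
                                      genes, flank = 2000) {
  scope <- match.arg(scope)
  regions <- if (scope == "promoter") promoters_of(genes, flank)
             else cds_regions(genes)
  gp <- as_gr(regions)
  ga <- as_gr(alterations)
  hits <- GenomicRanges::findOverlaps(gp, ga, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (!length(qi)) stop("no alterations overlap the scoped regions")
  dt <- data.table::data.table(gene_id = regions$payload[qi],
                               mark = alterations$mark[si],
                               stat = alterations$stat[si])
  stat <- NULL
  agg <- dt[, list(stat = mean(stat)), by = c("gene_id", "mark")]
  marks <- sort(unique(agg$mark))
  wide <- data.table::dcast(agg, gene_id ~ mark, value.var = "stat")
  r <- p <- n <- matrix(NA_real_, length(marks), length(marks),
                        dimnames = list(marks, marks))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_along(marks)) for (j in seq_along(marks)) {
    if (i >= j) next
    x <- wide[[marks[i]]]; y <- wide[[marks[j]]]
    ok <- !is.na(x) & !is.na(y)
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) >= 5L && sd(x[ok]) > 0 && sd(y[ok]) > 0) {
      ct <- cor.test(x[ok], y[ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  r_masked <- ifelse(!is.na(p) & p < 0.05, r, NA_real_)
  diag(n) <- NA_real_
  list(r = r_masked, r_raw = r, p = p, n = n)
}

#' Coding-sequence regions of genes
#'
#' The CDS scope is the union of a gene's exons minus its UTR intervals.
#'
#' @param genes gene-model data.frame.
#' @return interval data.frame with \code{payload} = gene_id.
#' @export
cds_regions <- function(genes) {
  genes <- normalize_gene_models(genes)
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    ex <- IRanges::IRanges(genes$exon_starts[[i]] + 1,
                           genes$exon_ends[[i]])
    utr <- IRanges::IRanges()
    if (!is.na(genes$utr5_start[i]))
      utr <- c(utr, IRanges::IRanges(genes$utr5_start[i] + 1,
                                     genes$utr5_end[i]))
    if (!is.na(genes$utr3_start[i]))
      utr <- c(utr, IRanges::IRanges(genes$utr3_start[i] + 1,
                                     genes$utr3_end[i]))
    cds <- IRanges::setdiff(IRanges::reduce(ex), utr)
    if (length(cds))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = genes$chrom[i], start = IRanges::start(cds) - 1,
        end = IRanges::end(cds), payload = genes$gene_id[i],
        stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(chrom = character(), start = numeric(),
                         end = numeric(), payload = character())
  class(out) <- c("bed_intervals", "data.frame")
  out
}
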