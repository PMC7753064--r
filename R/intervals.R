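#' Construct a BED-style interval table
#'
#' Intervals throughout the package are plain data frames in BED convention
#' (0-based start, half-open end) with columns \code{chrom}, \code{start},
#' \code{end} and optionally \code{strand} and \code{payload} (state label,
#' mark name, direction -- column 4 of a BED4 file).
#'
#' @param chrom character chromosome names.
#' @param start,end integer positions, 0-based half-open.
#' @param strand optional strand, one of \code{"+"}, \code{"-"}, \code{"."}.
#' @param payload optional opaque label carried in BED column 4.
#' @return a \code{data.frame} with class \code{"bed_intervals"} prepended.
#' @export
bed_intervals <- function(chrom, start, end, strand = NULL, payload = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (!is.null(strand)) df$strand <- as.character(strand)
  if (!is.null(payload)) df$payload <- payload
  validate_intervals(df)
  class(df) <- c("bed_intervals", "data.frame")
  df
}

#' Validate an interval table
#'
#' Checks the interval invariants (non-empty chrom, \code{start >= 0},
#' \code{end > start}) and fails naming the first offending record.
#'
#' @param df interval data.frame with chrom/start/end columns.
#' @return the input, invisibly.
#' @export
validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(is.na(df$chrom) | !nzchar(df$chrom) | df$start < 0 |
                 df$end <= df$start)
  if (length(bad)) {
    i <- bad[1L]
    stop(sprintf("malformed interval at record %d: %s:%s-%s",
                 i, df$chrom[i], format(df$start[i]), format(df$end[i])))
  }
  invisible(df)
}

## BED (0-based half-open) <-> GRanges (1-based closed)
as_gr <- function(df, keep = FALSE) {
  validate_intervals(df)
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[is.na(strand) | strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = strand)
  if (keep && "payload" %in% names(df)) gr$payload <- df$payload
  gr
}

gr_to_bed <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (!is.null(gr$payload)) df$payload <- gr$payload
  class(df) <- c("bed_intervals", "data.frame")
  df
}

#' Intersect two interval sets
#'
#' Returns the maximal set of intervals covered by both inputs, sorted and
#' non-overlapping within each chromosome. Total returned bp equals the
#' overlap bp between the two sets.
#'
#' @param a,b interval data.frames (BED convention).
#' @return interval data.frame of the intersection.
#' @export
bed_intersect <- function(a, b) {
  ga <- GenomicRanges::reduce(as_gr(a), ignore.strand = TRUE)
  gb <- GenomicRanges::reduce(as_gr(b), ignore.strand = TRUE)
  gr_to_bed(GenomicRanges::sort(suppressWarnings(
    GenomicRanges::intersect(ga, gb, ignore.strand = TRUE))))
}

#' Total bases covered by an interval set
#' @param a interval data.frame.
#' @return numeric bp after merging overlaps.
#' @export
bed_coverage_bp <- function(a) {
  if (nrow(a) == 0L) return(0)
  sum(GenomicRanges::width(GenomicRanges::reduce(as_gr(a),
                                                 ignore.strand = TRUE)))
}

#' Two-sided Fisher exact p on a 2x2 table
#'
#' The two-tail rule sums, at fixed margins, the probabilities of all
#' tables no more likely than the observed one. This is the p-value
#' \code{\link{fisher_colocalization}} reports on its overlap table.
#'
#' @param tab 2x2 numeric matrix of counts.
#' @return two-sided p-value.
#' @export
fisher_two_tail <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L))
  fisher.test(tab, alternative = "two.sided")$p.value
}

#' Co-localization significance of two interval sets
#'
#' Tests whether intervals of \code{a} overlap intervals of \code{b} more than
#' expected by chance, in the spirit of interval-overlap Fisher tests on
#' BED files. The 2x2 table is: \code{n11} = a-intervals overlapping any
#' b-interval, \code{n12} = remaining a-intervals, \code{n21} = b-intervals
#' not overlapping any a-interval, and \code{n22} an estimate of the number of
#' genome slots carrying neither set,
#' \code{floor(genome_size / (mean_len(a) + mean_len(b)))} minus the other
#' three cells (floored at 0).
#'
#' @param a,b interval data.frames.
#' @param genome_size total genome length in bp.
#' @return list with \code{table} (2x2 integer matrix) and \code{p_two_tail}.
#' @export
fisher_colocalization <- function(a, b, genome_size) {
  if (nrow(a) == 0L || nrow(b) == 0L) stop("degenerate contingency table")
  ga <- as_gr(a); gb <- as_gr(b)
  n11 <- sum(IRanges::overlapsAny(ga, gb, ignore.strand = TRUE))
  n12 <- length(ga) - n11
  n21 <- sum(!IRanges::overlapsAny(gb, ga, ignore.strand = TRUE))
  slots <- floor(genome_size / (mean(a$end - a$start) + mean(b$end - b$start)))
  n22 <- max(0, slots - n11 - n12 - n21)
  tab <- matrix(as.numeric(c(n11, n12, n21, n22)), 2L, 2L, byrow = TRUE,
                dimnames = list(c("a", "not_a"), c("b", "not_b")))
  list(table = tab, p_two_tail = fisher_two_tail(tab))
}

#' Promoter windows around transcription start sites
#'
#' The promoter of a gene is the symmetric window \code{[tss - flank,
#' tss + flank)}, clipped at position 0. Strand determines where the TSS is
#' (gene start on \code{+}, gene end on \code{-}) but does not flip the
#' window.
#'
#' @param genes gene-model data.frame (see \code{\link{read_gene_models}});
#'   needs columns \code{gene_id}, \code{chrom}, \code{strand},
#'   \code{tx_start}, \code{tx_end} (or a precomputed \code{tss}).
#' @param flank half-width in bp (default 2000).
#' @return interval data.frame with \code{payload} = gene_id.
#' @export
promoters_of <- function(genes, flank = 2000) {
  stopifnot(flank > 0)
  tss <- gene_tss(genes)
  bed_intervals(genes$chrom, pmax(0, tss - flank), tss + flank,
                payload = genes$gene_id)
}

gene_tss <- function(genes) {
  if (!is.null(genes$tss)) return(genes$tss)
  ifelse(genes$strand == "-", genes$tx_end, genes$tx_start)
}

gene_tes <- function(genes) {
  ifelse(genes$strand == "-", genes$tx_start, genes$tx_end)
}

.feature_levels <- c("Promoter(<1kb)", "Promoter(1-2kb)", "UTR5", "UTR3",
                     "FirstExon", "OtherExon", "FirstIntron", "OtherIntron",
                     "Downstream", "DistalIntergenic")

## Category of point p (0-based) relative to one gene row; NA_integer_ if the
## point falls in none of the gene's features. Returns an index into
## .feature_levels (priority order == level order).
.point_gene_feature <- function(p, g) {
  if (p$chrom != g$chrom) return(NA_integer_)
  d <- abs(p$pos - g$tss)
  if (d < 1000) return(1L)
  if (d < 2000) return(2L)
  within <- function(s, e) p$pos >= s & p$pos < e
  if (!is.na(g$utr5_start) && within(g$utr5_start, g$utr5_end)) return(3L)
  if (!is.na(g$utr3_start) && within(g$utr3_start, g$utr3_end)) return(4L)
  es <- g$exon_starts[[1L]]; ee <- g$exon_ends[[1L]]
  hit <- which(p$pos >= es & p$pos < ee)
  if (length(hit)) {
    first_ex <- if (g$strand == "-") length(es) else 1L
    return(if (hit[1L] == first_ex) 5L else 6L)
  }
  if (length(es) > 1L) {
    is_ <- ee[-length(ee)]; ie <- es[-1L]
    ihit <- which(p$pos >= is_ & p$pos < ie)
    if (length(ihit)) {
      first_in <- if (g$strand == "-") length(is_) else 1L
      return(if (ihit[1L] == first_in) 7L else 8L)
    }
  }
  tes <- g$tes
  down <- if (g$strand == "-") p$pos >= tes - 3000 & p$pos < tes
          else p$pos >= tes & p$pos < tes + 3000
  if (down) return(9L)
  NA_integer_
}

#' Annotate intervals with a single genomic feature each
#'
#' Assigns every interval exactly one feature category, judged at the
#' interval midpoint, by fixed priority: Promoter(<1kb) > Promoter(1-2kb) >
#' UTR5 > UTR3 > FirstExon > OtherExon > FirstIntron > OtherIntron >
#' Downstream (within 3 kb past the gene end) > DistalIntergenic. Promoter
#' categories measure unsigned midpoint-to-TSS distance. Ties between genes
#' offering the same category are broken by nearest TSS, then lexicographic
#' gene id.
#'
#' @param ivs interval data.frame to annotate.
#' @param genes gene-model data.frame.
#' @return data.frame with columns \code{feature} (factor over the ten
#'   categories) and \code{gene_id} (NA for DistalIntergenic).
#' @export
annotate_features <- function(ivs, genes) {
  validate_intervals(ivs)
  if (is.null(genes) || nrow(genes) == 0L) {
    warning("empty gene list: all intervals annotated DistalIntergenic")
    return(data.frame(
      feature = factor(rep("DistalIntergenic", nrow(ivs)),
                       levels = .feature_levels),
      gene_id = rep(NA_character_, nrow(ivs)),
      stringsAsFactors = FALSE))
  }
  genes <- normalize_gene_models(genes)
  mids <- floor((ivs$start + ivs$end) / 2)
  feat <- integer(nrow(ivs)); gid <- character(nrow(ivs))
  for (k in seq_len(nrow(ivs))) {
    p <- list(chrom = ivs$chrom[k], pos = mids[k])
    ## genes whose extended footprint could contain the midpoint
    cand <- which(genes$chrom == p$chrom &
                    p$pos >= pmin(genes$tx_start, genes$tss - 2000) - 3000 &
                    p$pos < pmax(genes$tx_end, genes$tss + 2000) + 3000)
    best <- NA_integer_; best_gene <- NA_character_; best_d <- Inf
    for (j in cand) {
      f <- .point_gene_feature(p, genes[j, , drop = FALSE])
      if (is.na(f)) next
      d <- abs(p$pos - genes$tss[j])
      if (is.na(best) || f < best ||
          (f == best && (d < best_d ||
                         (d == best_d && genes$gene_id[j] < best_gene)))) {
        best <- f; best_gene <- genes$gene_id[j]; best_d <- d
      }
    }
    if (is.na(best)) { feat[k] <- 10L; gid[k] <- NA_character_ }
    else { feat[k] <- best; gid[k] <- best_gene }
  }
  data.frame(feature = factor(.feature_levels[feat], levels = .feature_levels),
             gene_id = gid, stringsAsFactors = FALSE)
}

#' Tabulate annotated features
#'
#' Summarizes \code{\link{annotate_features}} output as counts and fractions,
#' per region (default) and per bp.
#'
#' @param ivs interval data.frame.
#' @param genes gene-model data.frame.
#' @return data.frame with feature, n, frac_regions, bp, frac_bp.
#' @export
feature_distribution <- function(ivs, genes) {
  ann <- annotate_features(ivs, genes)
  bp <- ivs$end - ivs$start
  n <- tapply(rep(1, nrow(ivs)), ann$feature, sum, default = 0)
  b <- tapply(bp, ann$feature, sum, default = 0)
  data.frame(feature = factor(.feature_levels, levels = .feature_levels),
             n = as.vector(n), frac_regions = as.vector(n) / max(1, sum(n)),
             bp = as.vector(b), frac_bp = as.vector(b) / max(1, sum(b)))
}

#' Partition marked bases by the exact combination of marks covering them
#'
#' Given one interval set per epigenetic mark, partitions the union of all
#' marked bases by the subset of marks covering each base and reports bp per
#' combination. Combination names join mark names with \code{"+"} in the
#' order given. The bp values sum to the bp of the union.
#'
#' @param marked_regions named list of interval data.frames, one per mark.
#' @return named numeric vector, bp per observed combination.
#' @export
mark_combination_counts <- function(marked_regions) {
  stopifnot(length(marked_regions) >= 1L, !is.null(names(marked_regions)))
  marks <- names(marked_regions)
  grl <- lapply(marked_regions, function(df)
    GenomicRanges::reduce(as_gr(df), ignore.strand = TRUE))
  all_gr <- GenomicRanges::disjoin(unlist(methods::as(grl, "GRangesList")),
                                   ignore.strand = TRUE)
  if (length(all_gr) == 0L) return(setNames(numeric(0), character(0)))
  member <- vapply(grl, function(g)
    IRanges::overlapsAny(all_gr, g, ignore.strand = TRUE),
    logical(length(all_gr)))
  member <- matrix(member, nrow = length(all_gr),
                   dimnames = list(NULL, marks))
  combo <- apply(member, 1L, function(z) paste(marks[z], collapse = "+"))
  keep <- nzchar(combo)
  res <- tapply(GenomicRanges::width(all_gr)[keep], combo[keep], sum)
  setNames(as.vector(res), names(res))
}
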