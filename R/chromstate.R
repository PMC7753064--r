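#' The 19-state chromatin vocabulary
#'
#' A named preset of 19 chromatin-state labels with functional group
#' annotations: promoter (states 1-4), transcribed (5-8), enhancer (9-14),
#' ZNF genes (15), bivalent TSS (16), bivalent/weak enhancer (17), polycomb
#' repressed (18) and quiescent (19).
#'
#' @return data.frame with columns \code{state} (\code{"E1"..."E19"}) and
#'   \code{group}.
#' @export
chromhmm19_states <- function() {
  data.frame(
    state = paste0("E", 1:19),
    group = c(rep("promoter", 4), rep("transcribed", 4), rep("enhancer", 6),
              "znf", "bivalent_tss", "bivalent_weak_enhancer", "polycomb",
              "quiescent"),
    stringsAsFactors = FALSE)
}

#' Bin a chromatin-state segmentation onto a fixed grid
#'
#' Projects a segmentation (non-overlapping labeled intervals) onto bins of
#' \code{bin_size} bp. A bin wholly inside one state interval takes that
#' state; a bin straddling states takes the state covering the majority of
#' its covered bases, ties going to the state found leftmost in the bin.
#' Bins with no coverage are absent from the track. Segmentation tools emit
#' intervals in multiples of the bin size, so the majority rule rarely fires
#' on real segmentations.
#'
#' @param seg interval data.frame whose \code{payload} column holds the state
#'   label.
#' @param bin_size bin width in bp (default 200).
#' @return a \code{binned_track}: data.frame (chrom, bin, state) with
#'   attribute \code{bin_size}; \code{bin} is the 0-based bin index, so the
#'   bin spans \code{[bin * bin_size, (bin + 1) * bin_size)}.
#' @export
bin_segmentation <- function(seg, bin_size = 200) {
  validate_intervals(seg)
  stopifnot(bin_size >= 1)
  if (is.null(seg$payload)) stop("segmentation needs a state label payload")
  if (nrow(seg) == 0L) return(empty_track(bin_size))
  ## overlapping intervals invalidate a segmentation
  o <- order(seg$chrom, seg$start)
  ss <- seg[o, ]
  same <- ss$chrom[-1L] == ss$chrom[-nrow(ss)]
  clash <- which(same & ss$start[-1L] < ss$end[-nrow(ss)])
  if (length(clash)) {
    i <- clash[1L]
    stop(sprintf("overlapping segmentation intervals: %s:%s-%s and %s:%s-%s",
                 ss$chrom[i], format(ss$start[i]), format(ss$end[i]),
                 ss$chrom[i + 1L], format(ss$start[i + 1L]),
                 format(ss$end[i + 1L])))
  }
  b0 <- floor(seg$start / bin_size)
  b1 <- floor((seg$end - 1) / bin_size)
  nb <- b1 - b0 + 1L
  idx <- rep(seq_len(nrow(seg)), nb)
  bin <- b0[idx] + sequence(nb) - 1
  lo <- pmax(seg$start[idx], bin * bin_size)
  hi <- pmin(seg$end[idx], (bin + 1) * bin_size)
  dt <- data.table::data.table(chrom = seg$chrom[idx], bin = bin,
                               state = as.character(seg$payload[idx]),
                               cover = hi - lo, left = lo)
  ## aggregate split intervals of the same state, then majority vote
  cover <- left <- NULL  # data.table NSE
  agg <- dt[, list(cover = sum(cover), left = min(left)),
            by = c("chrom", "bin", "state")]
  data.table::setorderv(agg, c("chrom", "bin", "cover", "left"),
                        order = c(1L, 1L, -1L, 1L))
  win <- agg[!duplicated(agg, by = c("chrom", "bin"))]
  data.table::setorderv(win, c("chrom", "bin"))
  out <- data.frame(chrom = win$chrom, bin = win$bin, state = win$state,
                    stringsAsFactors = FALSE)
  structure(out, bin_size = bin_size, class = c("binned_track", "data.frame"))
}

#' Construct a binned state track directly
#'
#' Mainly useful for simulations and tests; \code{\link{bin_segmentation}}
#' is the usual entry point.
#'
#' @param chrom,bin,state parallel vectors: chromosome, 0-based bin index,
#'   state label.
#' @param bin_size bin width in bp.
#' @return a \code{binned_track}.
#' @export
binned_track <- function(chrom, bin, state, bin_size = 200) {
  df <- data.frame(chrom = as.character(chrom), bin = as.numeric(bin),
                   state = as.character(state), stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("chrom", "bin")])) stop("duplicate bins")
  structure(df, bin_size = bin_size, class = c("binned_track",
                                               "data.frame"))
}

empty_track <- function(bin_size) {
  structure(data.frame(chrom = character(), bin = numeric(),
                       state = character(), stringsAsFactors = FALSE),
            bin_size = bin_size, class = c("binned_track", "data.frame"))
}

track_states <- function(track) sort(unique(track$state))

#' Joint state occupancy of two binned tracks
#'
#' Counts bins by their (normal state, tumor state) assignment over the bins
#' covered in both tracks. Bins present in only one track are excluded and
#' their number reported.
#'
#' @param normal,tumor \code{binned_track}s on the same bin grid.
#' @param states optional ordered state labels for the matrix axes; defaults
#'   to the sorted union of the labels seen in either track.
#' @return a \code{transition_enrichment} object: list with \code{states},
#'   \code{observed} matrix (rows = normal, cols = tumor),
#'   \code{total_bins}, \code{n_excluded}, and empty slots for
#'   \code{expected}, \code{res}, \code{nes}.
#' @export
joint_occupancy <- function(normal, tumor, states = NULL) {
  bsn <- attr(normal, "bin_size"); bst <- attr(tumor, "bin_size")
  if (!identical(bsn, bst))
    stop("bin_size mismatch: ", bsn, " vs ", bst)
  if (is.null(states))
    states <- sort(unique(c(normal$state, tumor$state)))
  key_n <- paste(normal$chrom, normal$bin)
  key_t <- paste(tumor$chrom, tumor$bin)
  m <- match(key_n, key_t)
  shared <- !is.na(m)
  observed <- unclass(table(
    factor(normal$state[shared], levels = states),
    factor(tumor$state[m[shared]], levels = states)))
  names(dimnames(observed)) <- NULL
  n_excl <- sum(!shared) + sum(!(key_t %in% key_n))
  structure(list(states = states, observed = observed, expected = NULL,
                 res = NULL, nes = NULL, total_bins = sum(observed),
                 n_excluded = n_excl, bin_size = bsn),
            class = "transition_enrichment")
}

#' Raw enrichment score of state transitions
#'
#' Fills the expected-count and RES matrices of a
#' \code{transition_enrichment}. Under the null that the normal-sample state
#' and tumor-sample state of a bin are independent,
#' \code{expected[i,j] = normal_marginal_i * tumor_marginal_j / total_bins},
#' and \code{RES[i,j] = observed[i,j] / expected[i,j]}. Entries with zero
#' expectation are flagged \code{NA}.
#'
#' @param te \code{transition_enrichment} with observed counts.
#' @return the object with \code{expected} and \code{res} filled.
#' @export
raw_enrichment <- function(te) {
  stopifnot(inherits(te, "transition_enrichment"))
  if (te$total_bins == 0L) stop("no co-covered bins: total_bins = 0")
  rn <- rowSums(te$observed); cn <- colSums(te$observed)
  te$expected <- outer(rn, cn) / te$total_bins
  te$res <- ifelse(te$expected > 0, te$observed / te$expected, NA_real_)
  te
}

#' Normalized enrichment score of state transitions
#'
#' \code{NES[i,j] = RES[i,j] / RES[j,i]}: the enrichment of the i-to-j
#' transition relative to the reverse transition. Values above 1 indicate a
#' directional preference. Entries where the reverse RES is zero or either
#' side is undefined are flagged \code{NA} (never infinite) so downstream
#' ranking skips them; the diagonal is 1 wherever \code{RES[i,i] > 0}.
#'
#' @param te \code{transition_enrichment} with \code{res} filled (see
#'   \code{\link{raw_enrichment}}).
#' @return the object with \code{nes} filled.
#' @export
normalized_enrichment <- function(te) {
  stopifnot(inherits(te, "transition_enrichment"), !is.null(te$res))
  rev <- t(te$res)
  nes <- ifelse(!is.na(te$res) & !is.na(rev) & rev > 0, te$res / rev,
                NA_real_)
  diag(nes) <- ifelse(!is.na(diag(te$res)) & diag(te$res) > 0, 1, NA_real_)
  te$nes <- nes
  te
}

#' Chi-square test of state independence
#'
#' Pearson's chi-square test of independence on the joint occupancy matrix,
#' after dropping all-zero rows and columns.
#'
#' @param te \code{transition_enrichment} with observed counts.
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
chisq_independence <- function(te) {
  stopifnot(inherits(te, "transition_enrichment"))
  obs <- te$observed
  obs <- obs[rowSums(obs) > 0, colSums(obs) > 0, drop = FALSE]
  if (nrow(obs) < 2L || ncol(obs) < 2L) stop("degenerate table")
  ht <- suppressWarnings(chisq.test(obs, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Genes whose promoters harbor a given state transition
#'
#' Returns the ids of genes whose promoter window (\code{tss +/- flank})
#' contains at least one bin assigned \code{from_state} in the normal track
#' and \code{to_state} in the tumor track.
#'
#' @param normal,tumor \code{binned_track}s on the same grid.
#' @param from_state,to_state state labels.
#' @param genes gene-model data.frame.
#' @param flank promoter half-width in bp (default 2000).
#' @return sorted, deduplicated character vector of gene ids.
#' @export
transition_genes <- function(normal, tumor, from_state, to_state, genes,
                             flank = 2000) {
  known <- sort(unique(c(normal$state, tumor$state)))
  for (s in c(from_state, to_state))
    if (!s %in% known)
      stop("unknown state label '", s, "'; known states: ",
           paste(known, collapse = ", "))
  bs <- attr(normal, "bin_size")
  if (!identical(bs, attr(tumor, "bin_size"))) stop("bin_size mismatch")
  key_n <- paste(normal$chrom, normal$bin)
  key_t <- paste(tumor$chrom, tumor$bin)
  m <- match(key_n, key_t)
  hit <- which(!is.na(m) & normal$state == from_state &
                 tumor$state[m] == to_state)
  if (!length(hit)) return(character(0))
  bins <- bed_intervals(normal$chrom[hit], normal$bin[hit] * bs,
                        (normal$bin[hit] + 1) * bs)
  prom <- promoters_of(genes, flank)
  ov <- IRanges::overlapsAny(as_gr(prom), as_gr(bins), ignore.strand = TRUE)
  sort(unique(prom$payload[ov]))
}

#' @export
print.transition_enrichment <- function(x, ...) {
  cat("transition_enrichment:", length(x$states), "states,",
      x$total_bins, "co-covered bins (", x$n_excluded, "excluded )\n")
  filled <- c("observed", if (!is.null(x$expected)) "expected",
              if (!is.null(x$res)) "res", if (!is.null(x$nes)) "nes")
  cat("matrices:", paste(filled, collapse = ", "), "\n")
  invisible(x)
}

#' Write transition matrices as TSV
#'
#' Writes the observed, expected, RES and NES matrices (those that are
#' filled) as TSV files with state labels as row/column headers.
#'
#' @param te \code{transition_enrichment}.
#' @param prefix output path prefix; files are named
#'   \code{<prefix>_observed.tsv} etc.
#' @return character vector of paths written, invisibly.
#' @export
write_transition_matrices <- function(te, prefix) {
  paths <- character(0)
  for (slot in c("observed", "expected", "res", "nes")) {
    m <- te[[slot]]
    if (is.null(m)) next
    p <- paste0(prefix, "_", slot, ".tsv")
    write.table(data.frame(state = te$states, m, check.names = FALSE),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
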