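# Independent brute-force oracles used across the suite. These recompute
# quantities from first principles (per-base membership, exhaustive
# enumeration, hand formulas) and must stay independent of the package's
# own code paths.

# set of (chrom, base) keys covered by an interval table
oracle_bases <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  unlist(lapply(seq_len(nrow(df)), function(i)
    paste(df$chrom[i], seq(df$start[i], df$end[i] - 1L))))
}

# per-base state map: named vector base-key -> state
oracle_state_map <- function(seg) {
  keys <- oracle_bases(seg)
  states <- rep(seg$payload, seg$end - seg$start)
  setNames(states, keys)
}

# bin a per-base state map: majority state per bin, leftmost-base tie-break
oracle_bin_map <- function(seg, bin_size = 200) {
  out <- list()
  for (chrom in unique(seg$chrom)) {
    s <- seg[seg$chrom == chrom, , drop = FALSE]
    pos <- unlist(mapply(function(a, b) seq(a, b - 1L), s$start, s$end,
                         SIMPLIFY = FALSE))
    st <- rep(s$payload, s$end - s$start)
    o <- order(pos); pos <- pos[o]; st <- st[o]
    for (b in unique(pos %/% bin_size)) {
      in_bin <- pos %/% bin_size == b
      cnt <- table(st[in_bin])
      top <- names(cnt)[cnt == max(cnt)]
      if (length(top) > 1L) {
        # leftmost covered base among tied states decides
        firsts <- vapply(top, function(x) min(pos[in_bin & st == x]), 0)
        top <- top[which.min(firsts)]
      }
      out[[paste(chrom, b)]] <- top
    }
  }
  unlist(out)
}

# joint counts + res + nes from two bin maps (named state vectors)
oracle_res_nes <- function(map_n, map_t, states) {
  shared <- intersect(names(map_n), names(map_t))
  obs <- matrix(0, length(states), length(states),
                dimnames = list(states, states))
  for (k in shared)
    obs[map_n[[k]], map_t[[k]]] <- obs[map_n[[k]], map_t[[k]]] + 1
  total <- length(shared)
  exp_ <- outer(rowSums(obs), colSums(obs)) / total
  res <- ifelse(exp_ > 0, obs / exp_, NA_real_)
  nes <- matrix(NA_real_, length(states), length(states),
                dimnames = list(states, states))
  for (i in seq_along(states)) for (j in seq_along(states)) {
    if (i == j) {
      nes[i, j] <- if (!is.na(res[i, i]) && res[i, i] > 0) 1 else NA_real_
    } else if (!is.na(res[i, j]) && !is.na(res[j, i]) && res[j, i] > 0) {
      nes[i, j] <- res[i, j] / res[j, i]
    }
  }
  list(observed = obs, res = res, nes = nes, total = total)
}

# two-sided Fisher p by enumeration over all tables with the same margins:
# sum the probabilities of tables no more likely than the observed one
oracle_fisher2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(ks, function(k)
    exp(lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1)), 0)
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# upper-tail hypergeometric by explicit summation
oracle_hyper_upper <- function(k, K, N, n) {
  ks <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(vapply(ks, function(i)
    exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)), 0))
}

# Yates chi-square by the hand formula sum((|o-e|-0.5)^2/e)
oracle_yates <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((abs(tab - e) - 0.5)^2 / e)
}

# Cohen's kappa from two membership vectors, by the hand formula
oracle_kappa <- function(ina, inb) {
  N <- length(ina)
  po <- mean(ina == inb)
  pe <- (sum(ina) * sum(inb) + sum(!ina) * sum(!inb)) / N^2
  (po - pe) / (1 - pe)
}

# all-pairs shortest paths by Floyd-Warshall on an adjacency matrix
oracle_shortest_paths <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj, 1, Inf); diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n))
    d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
  d
}

oracle_harmonic_closeness <- function(adj) {
  d <- oracle_shortest_paths(adj)
  diag(d) <- Inf
  rowSums(1 / d)
}

# empirical survival function (no censoring): fraction surviving past t
oracle_empirical_surv <- function(times, t) mean(times > t)

# the independent restatement of the active/poised/repressive voting rule
oracle_subgroup <- function(marks, directions) {
  act <- c("H3K4me1", "H3K4me3", "H3K27ac", "H3K36me3")
  votes <- ifelse(marks %in% act, directions == "up", directions == "down")
  if (all(votes)) "active" else if (all(!votes)) "repressive" else "poised"
}

# small random segmentation over a toy genome, arbitrary breakpoints
random_segmentation <- function(genome_len, n_states, seed,
                                chrom = "chrT") {
  set.seed(seed)
  n_cut <- sample(5:15, 1L)
  cuts <- sort(sample(seq(50, genome_len - 50, by = 10), n_cut))
  bounds <- unique(c(0, cuts, genome_len))
  data.frame(chrom = chrom, start = bounds[-length(bounds)],
             end = bounds[-1L],
             payload = sample(paste0("S", seq_len(n_states)),
                              length(bounds) - 1L, replace = TRUE),
             stringsAsFactors = FALSE)
}
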