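#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults emulate the
#' processed products of a paired tumor/normal gastric epigenome study: a
#' 19-state segmentation with one predominant planted transition (weak TSS
#' to active TSS at 30% of source bins), six promoter mark types whose
#' per-mark expression effect is +/- 0.5 log2 units, hypermethylation biased
#' into CpG islands, negative methylation-expression coupling, 19 matched
#' tumor/normal expression pairs, and a survival cohort with planted
#' per-gene, per-subtype hazards.
#'
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#' @param genome data.frame (chrom, length) in bp.
#' @param n_genes number of genes to place.
#' @param n_patients matched tumor/normal pairs in the expression table.
#' @param state_labels chromatin-state vocabulary.
#' @param transition_plants data.frame (from, to, fraction): rewrite that
#'   fraction of from-state bins to the to-state in the tumor track.
#' @param state_noise background discordance rate: each tumor bin is
#'   redrawn uniformly from the state set with this probability before the
#'   planted rewrites, emulating the biological and technical state changes
#'   seen between any two real segmentations.
#' @param mark_effects named numeric, absolute log2 expression effect per
#'   altered mark.
#' @param p_marked probability a gene carries any altered mark.
#' @param n_marks_probs distribution of the altered-mark count (1..6) for
#'   marked genes.
#' @param program_probs probabilities of the per-gene regulatory program:
#'   all-activating, all-silencing, mixed.
#' @param colocalization_rate excess probability that a mixed program's
#'   votes agree (inflates mark co-occurrence direction agreement).
#' @param cgi_bias probability a hypermethylated position is flagged CGI
#'   (and a hypomethylated one non-CGI).
#' @param meth_expr_r target methylation-expression correlation for
#'   \code{\link{sim_meth_expr}}.
#' @param expr_sd per-sample expression noise, log2 units.
#' @param hub_plants number of genes forced to high degree in the PPI graph.
#' @param hazard_plants data.frame (gene, subtype, beta): per-unit
#'   log-hazard of standardized expression; subtype \code{"ALL"} applies to
#'   every sample. Gene ids here are 1-based indices into the generated gene
#'   list when numeric.
#' @param n_surv survival cohort size.
#' @param censor_rate expected fraction of censored subjects.
#' @return list with class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1,
                       genome = data.frame(chrom = c("chr1", "chr2"),
                                           length = c(3.6e6, 2.4e6)),
                       n_genes = 400,
                       n_patients = 19,
                       state_labels = chromhmm19_states()$state,
                       transition_plants = data.frame(
                         from = "E4", to = "E1", fraction = 0.3),
                       state_noise = 0.05,
                       mark_effects = setNames(rep(0.5, 6), epi_marks()),
                       p_marked = 0.7,
                       n_marks_probs = c(0.35, 0.25, 0.18, 0.12, 0.07, 0.03),
                       program_probs = c(activating = 0.4, silencing = 0.4,
                                         mixed = 0.2),
                       colocalization_rate = 0.5,
                       cgi_bias = 0.9,
                       meth_expr_r = -0.4,
                       expr_sd = 0.5,
                       hub_plants = 5,
                       hazard_plants = data.frame(
                         gene = c(1, 2), subtype = c("ALL", "CIN"),
                         beta = c(1.0, 1.0)),
                       n_surv = 400,
                       censor_rate = 0.3) {
  stopifnot(all(transition_plants$fraction >= 0 &
                  transition_plants$fraction <= 1),
            censor_rate >= 0, censor_rate <= 1,
            abs(sum(n_marks_probs) - 1) < 1e-8)
  structure(as.list(environment()), class = "sim_config")
}

## derived sub-seed, kept well under 2^31
.subseed <- function(cfg, k) (cfg$seed %% 1000000L) * 1000L + k

#' Generate a genome and non-overlapping gene models
#'
#' Places \code{n_genes} genes with random strand, 2-5 exons, and short
#' terminal UTRs, leaving inter-gene gaps so promoters rarely collide.
#'
#' @param cfg \code{sim_config}.
#' @return list with \code{genome} (chrom, length) and \code{genes}
#'   (normalized gene-model data.frame).
#' @export
make_genome_and_genes <- function(cfg) {
  stopifnot(cfg$n_genes >= 1)
  set.seed(.subseed(cfg, 1L))
  rows <- list()
  chrom_i <- 1L
  cursor <- 3000
  for (k in seq_len(cfg$n_genes)) {
    len <- round(runif(1, 3000, 12000))
    ## min gap 4000 keeps a gene's promoter clear of the neighbour's
    ## promoter-planted alterations (TSS separation >= 3900 suffices)
    gap <- round(runif(1, 4000, 8000))
    while (chrom_i <= nrow(cfg$genome) &&
           cursor + gap + len + 3000 > cfg$genome$length[chrom_i]) {
      chrom_i <- chrom_i + 1L
      cursor <- 3000
    }
    if (chrom_i > nrow(cfg$genome))
      stop("genome too small for ", cfg$n_genes, " genes")
    start <- cursor + gap
    end <- start + len
    cursor <- end
    n_ex <- sample(2:5, 1L)
    cuts <- sort(sample(seq(start + 200, end - 200, by = 50),
                        2L * n_ex - 2L))
    bounds <- c(start, cuts, end)
    es <- bounds[seq(1L, length(bounds) - 1L, by = 2L)]
    ee <- bounds[seq(2L, length(bounds), by = 2L)]
    strand <- sample(c("+", "-"), 1L)
    u5len <- min(150, floor((ee[1L] - es[1L]) / 3))
    u3len <- min(150, floor((ee[n_ex] - es[n_ex]) / 3))
    if (strand == "+") {
      u5 <- c(es[1L], es[1L] + u5len); u3 <- c(ee[n_ex] - u3len, ee[n_ex])
    } else {
      u5 <- c(ee[n_ex] - u5len, ee[n_ex]); u3 <- c(es[1L], es[1L] + u3len)
    }
    rows[[k]] <- data.frame(
      gene_id = sprintf("g%04d", k), chrom = cfg$genome$chrom[chrom_i],
      strand = strand, tx_start = start, tx_end = end,
      exon_starts = paste(es, collapse = ","),
      exon_ends = paste(ee, collapse = ","),
      utr5_start = u5[1L], utr5_end = u5[2L],
      utr3_start = u3[1L], utr3_end = u3[2L], stringsAsFactors = FALSE)
  }
  list(genome = cfg$genome, genes = normalize_gene_models(do.call(rbind,
                                                                  rows)))
}

#' Generate paired normal/tumor chromatin-state segmentations
#'
#' The normal track is a first-order spatial chain over 200-bp bins (stay
#' probability 0.85). The tumor track copies it and rewrites each planted
#' (from, to) pair on the configured fraction of from-state bins, chosen at
#' random. Segmentations are emitted as BED4 interval tables in 200-bp
#' multiples.
#'
#' @param cfg \code{sim_config}.
#' @return list with \code{normal}, \code{tumor} (interval data.frames with
#'   state payloads) and \code{truth} (per-plant rewritten-bin counts).
#' @export
make_segmentations <- function(cfg) {
  stopifnot(length(cfg$state_labels) >= 2L)
  set.seed(.subseed(cfg, 2L))
  bs <- 200L
  seg_rows_n <- list(); seg_rows_t <- list()
  truth <- list()
  for (ci in seq_len(nrow(cfg$genome))) {
    chrom <- cfg$genome$chrom[ci]
    n_bins <- floor(cfg$genome$length[ci] / bs)
    states <- character(n_bins)
    s <- sample(cfg$state_labels, 1L)
    for (b in seq_len(n_bins)) {
      if (b > 1L && runif(1) > 0.85)
        s <- sample(setdiff(cfg$state_labels, s), 1L)
      states[b] <- s
    }
    tumor <- states
    if (cfg$state_noise > 0) {
      flip <- which(runif(n_bins) < cfg$state_noise)
      tumor[flip] <- sample(cfg$state_labels, length(flip), replace = TRUE)
    }
    for (pi in seq_len(nrow(cfg$transition_plants))) {
      pl <- cfg$transition_plants[pi, ]
      idx <- which(states == pl$from)
      n_rw <- floor(pl$fraction * length(idx))
      if (n_rw > 0L) {
        rw <- sample(idx, n_rw)
        tumor[rw] <- pl$to
      } else rw <- integer(0)
      key <- paste0(chrom, ":", pl$from, ">", pl$to)
      truth[[key]] <- length(rw)
    }
    to_bed <- function(v) {
      r <- rle(v)
      e <- cumsum(r$lengths) * bs
      s0 <- c(0, e[-length(e)])
      data.frame(chrom = chrom, start = s0, end = e, payload = r$values,
                 stringsAsFactors = FALSE)
    }
    seg_rows_n[[ci]] <- to_bed(states)
    seg_rows_t[[ci]] <- to_bed(tumor)
  }
  mk <- function(rows) {
    df <- do.call(rbind, rows)
    class(df) <- c("bed_intervals", "data.frame")
    df
  }
  list(normal = mk(seg_rows_n), tumor = mk(seg_rows_t),
       truth = list(rewritten_bins = truth,
                    plants = cfg$transition_plants))
}

#' Generate differential mark regions and methylated positions
#'
#' Each gene is marked with probability \code{p_marked}; marked genes draw
#' an altered-mark count from \code{n_marks_probs} and a regulatory program
#' (all-activating, all-silencing, or mixed). Activating votes put active
#' marks up and repressive marks (H3K27me3, mC) down, and vice versa;
#' mixed-program votes are Bernoulli with agreement inflated by
#' \code{colocalization_rate}. Histone alterations become promoter regions
#' with signed effect sizes; mC becomes 1-4 promoter DMPs whose delta-beta
#' sign follows the vote, with hypermethylated positions flagged CGI at rate
#' \code{cgi_bias}.
#'
#' @param cfg \code{sim_config}.
#' @param genes gene-model data.frame from
#'   \code{\link{make_genome_and_genes}}.
#' @return list with \code{alterations}, \code{dmps} and \code{truth}
#'   (per-gene marks, votes, program and planted log2 expression effect).
#' @export
make_marks_and_methylation <- function(cfg, genes) {
  set.seed(.subseed(cfg, 3L))
  marks <- epi_marks()
  alt <- list(); dmp <- list(); tr <- list()
  cpg_i <- 0L
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    if (runif(1) > cfg$p_marked) {
      tr[[k]] <- data.frame(gene_id = g$gene_id, n_marks = 0L,
                            program = NA_character_, effect = 0,
                            stringsAsFactors = FALSE)
      next
    }
    nm <- sample(seq_along(cfg$n_marks_probs), 1L,
                 prob = cfg$n_marks_probs)
    gm <- sample(marks, nm)
    program <- sample(names(cfg$program_probs), 1L,
                      prob = cfg$program_probs)
    votes <- switch(program,
      activating = rep(TRUE, nm),
      silencing = rep(FALSE, nm),
      mixed = {
        base <- runif(1) < 0.5
        agree <- runif(nm) < 0.5 + cfg$colocalization_rate / 2
        ifelse(agree, base, !base)
      })
    eff <- 0
    tss <- g$tss
    for (mi in seq_len(nm)) {
      mk <- gm[mi]; vote <- votes[mi]
      eff <- eff + ifelse(vote, 1, -1) * cfg$mark_effects[[mk]]
      ## direction: activating vote = active mark up / repressive mark down
      up <- if (mk %in% c("H3K27me3", "mC")) !vote else vote
      if (mk == "mC") {
        n_cpg <- sample(1:4, 1L)
        pos <- round(runif(n_cpg, max(0, tss - 1900), tss + 1900))
        db_sign <- if (up) 1 else -1
        db <- db_sign * runif(n_cpg, 0.1, 0.6)
        in_cgi <- ifelse(db > 0, runif(n_cpg) < cfg$cgi_bias,
                         runif(n_cpg) < 1 - cfg$cgi_bias)
        dmp[[length(dmp) + 1L]] <- data.frame(
          cpg_id = sprintf("cg%06d", cpg_i + seq_len(n_cpg)),
          chrom = g$chrom, pos = pos, delta_beta = db,
          q = runif(n_cpg, 0, 0.049), in_cgi = in_cgi,
          stringsAsFactors = FALSE)
        cpg_i <- cpg_i + n_cpg
      } else {
        w <- round(runif(1, 300, 1200))
        s0 <- round(runif(1, max(0, tss - 1900), tss + 1900 - w))
        stat_sign <- if (up) 1 else -1
        alt[[length(alt) + 1L]] <- data.frame(
          mark = mk, chrom = g$chrom, start = s0, end = s0 + w,
          direction = if (up) "up" else "down",
          stat = stat_sign * abs(rnorm(1, 1, 0.3)),
          q = runif(1, 0, 0.049), stringsAsFactors = FALSE)
      }
    }
    tr[[k]] <- data.frame(
      gene_id = g$gene_id, n_marks = nm, program = program, effect = eff,
      marks = paste(gm, collapse = ","),
      votes = paste(ifelse(votes, "a", "s"), collapse = ","),
      stringsAsFactors = FALSE)
  }
  truth <- data.table::rbindlist(tr, fill = TRUE)
  alterations <- if (length(alt)) do.call(rbind, alt) else
    data.frame(mark = character(), chrom = character(), start = numeric(),
               end = numeric(), direction = character(), stat = numeric(),
               q = numeric())
  dmps <- if (length(dmp)) do.call(rbind, dmp) else
    data.frame(cpg_id = character(), chrom = character(), pos = numeric(),
               delta_beta = numeric(), q = numeric(), in_cgi = logical())
  list(alterations = alterations, dmps = dmps,
       truth = as.data.frame(truth))
}

#' Generate a paired tumor/normal expression table
#'
#' Normal log2 FPKM is Gaussian around a per-gene baseline; tumor samples
#' add the gene's planted mark effect (sum of signed per-mark effects) plus
#' noise. FPKM is \code{2^log2}.
#'
#' @param cfg \code{sim_config}.
#' @param genes gene-model data.frame.
#' @param mark_truth truth table from
#'   \code{\link{make_marks_and_methylation}} (columns gene_id, effect).
#' @return \code{expression_table}.
#' @export
make_expression <- function(cfg, genes, mark_truth) {
  set.seed(.subseed(cfg, 4L))
  np <- cfg$n_patients
  mu <- rnorm(nrow(genes), 3, 1.5)
  eff <- mark_truth$effect[match(genes$gene_id, mark_truth$gene_id)]
  eff[is.na(eff)] <- 0
  ln <- matrix(rnorm(nrow(genes) * np, mu, cfg$expr_sd), ncol = np)
  lt <- matrix(rnorm(nrow(genes) * np, mu + eff, cfg$expr_sd), ncol = np)
  fpkm <- cbind(2^ln, 2^lt)
  rownames(fpkm) <- genes$gene_id
  colnames(fpkm) <- c(sprintf("N%02d", seq_len(np)),
                      sprintf("T%02d", seq_len(np)))
  pairing <- data.frame(patient = sprintf("P%02d", seq_len(np)),
                        normal = sprintf("N%02d", seq_len(np)),
                        tumor = sprintf("T%02d", seq_len(np)),
                        stringsAsFactors = FALSE)
  expression_table(fpkm, pairing)
}

#' Generate a PPI edge list and a survival cohort
#'
#' The graph is preferential-attachment (scale-free) over all genes, with
#' the first \code{hub_plants} genes forced to high degree by extra random
#' edges. Survival times are exponential with per-subject log-hazard equal
#' to the sum of planted beta times standardized expression of the planted
#' gene (applied to all samples for subtype \code{"ALL"}, otherwise only to
#' samples of that subtype), under independent exponential censoring tuned
#' to \code{censor_rate}.
#'
#' @param cfg \code{sim_config}.
#' @param genes gene-model data.frame.
#' @return list with \code{edges} (data.frame geneA, geneB), \code{surv}
#'   (\code{survival_data}) and \code{truth} (hazard plants, hub genes).
#' @export
make_ppi_and_survival <- function(cfg, genes) {
  set.seed(.subseed(cfg, 5L))
  n <- nrow(genes)
  g <- igraph::sample_pa(n, m = 2, directed = FALSE)
  igraph::V(g)$name <- genes$gene_id
  hubs <- genes$gene_id[seq_len(min(cfg$hub_plants, n))]
  extra <- list()
  for (h in hubs) {
    tgt <- sample(setdiff(genes$gene_id, h), min(40L, n - 1L))
    extra[[h]] <- data.frame(geneA = h, geneB = tgt,
                             stringsAsFactors = FALSE)
  }
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- unique(rbind(data.frame(geneA = el$from, geneB = el$to,
                                   stringsAsFactors = FALSE),
                        do.call(rbind, extra)))
  rownames(edges) <- NULL

  ns <- cfg$n_surv
  subtypes <- sample(c("CIN", "GS", "EBV", "MSI"), ns, replace = TRUE,
                     prob = c(0.35, 0.25, 0.2, 0.2))
  mu <- rnorm(n, 3, 1.5)
  z <- matrix(rnorm(n * ns), nrow = n,
              dimnames = list(genes$gene_id, sprintf("S%04d", seq_len(ns))))
  expr <- mu + z
  hp <- cfg$hazard_plants
  if (nrow(hp) && is.numeric(hp$gene))
    hp$gene <- genes$gene_id[hp$gene]
  loghaz <- rep(0, ns)
  for (i in seq_len(nrow(hp))) {
    sel <- if (hp$subtype[i] == "ALL") rep(TRUE, ns)
           else subtypes == hp$subtype[i]
    loghaz[sel] <- loghaz[sel] + hp$beta[i] * z[hp$gene[i], sel]
  }
  base <- 1 / 365
  t_ev <- rexp(ns, rate = base * exp(loghaz))
  if (cfg$censor_rate > 0 && cfg$censor_rate < 1) {
    t_cs <- rexp(ns, rate = base * cfg$censor_rate / (1 - cfg$censor_rate))
  } else if (cfg$censor_rate == 0) t_cs <- rep(Inf, ns)
  else t_cs <- t_ev * runif(ns)  # censor everything before the event
  time <- pmin(t_ev, t_cs)
  event <- as.integer(t_ev <= t_cs)
  clinical <- data.frame(sample_id = colnames(expr),
                         time = pmax(time, 0.5), event = event,
                         subtype = subtypes, stringsAsFactors = FALSE)
  list(edges = edges, surv = survival_data(clinical, expr),
       truth = list(hazard_plants = hp, hubs = hubs))
}

#' Bivariate-normal methylation/expression pairs
#'
#' Draws per-gene (promoter mean delta-beta, expression log2 fold change)
#' pairs from a bivariate normal with the given correlation; delta-beta is
#' scaled to a realistic magnitude well inside [-1, 1].
#'
#' @param n number of genes.
#' @param r target Pearson correlation.
#' @param seed RNG seed.
#' @return data.frame (delta_beta, log2fc).
#' @export
sim_meth_expr <- function(n, r = -0.4, seed = 1) {
  stopifnot(abs(r) <= 1)
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
  data.frame(delta_beta = pmax(-1, pmin(1, 0.2 * z1)), log2fc = z2)
}

#' Run every generator and optionally write the files
#'
#' Generates the full input set of the pipeline -- genome, gene models,
#' normal/tumor segmentations, differential mark regions, methylated
#' positions, paired expression, PPI edges, survival cohort -- together with
#' machine-readable ground truth. With \code{out_dir} set, writes each
#' product in its plain-text interchange format (BED4 segmentations, TSV
#' tables, JSON truth sidecar).
#'
#' @param cfg \code{sim_config}.
#' @param out_dir optional output directory.
#' @return named list of all generated objects and \code{truth}.
#' @export
simulate_study <- function(cfg = sim_config(), out_dir = NULL) {
  gg <- make_genome_and_genes(cfg)
  seg <- make_segmentations(cfg)
  mm <- make_marks_and_methylation(cfg, gg$genes)
  expr <- make_expression(cfg, gg$genes, mm$truth)
  ps <- make_ppi_and_survival(cfg, gg$genes)
  out <- list(genome = gg$genome, genes = gg$genes,
              seg_normal = seg$normal, seg_tumor = seg$tumor,
              alterations = mm$alterations, dmps = mm$dmps, expr = expr,
              ppi_edges = ps$edges, surv = ps$surv,
              truth = list(transitions = seg$truth, marks = mm$truth,
                           survival = ps$truth))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(out_dir, f)
    write_bed(out$seg_normal, fp("seg_normal.bed"))
    write_bed(out$seg_tumor, fp("seg_tumor.bed"))
    write_gene_models(out$genes, fp("genes.tsv"))
    write.table(out$alterations, fp("mark_alterations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(out$dmps, fp("dmps.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(gene_id = rownames(out$expr$fpkm),
                           out$expr$fpkm, check.names = FALSE),
                fp("fpkm.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(out$expr$pairing, fp("pairing.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(out$ppi_edges, fp("ppi_edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(out$surv$clinical, fp("survival.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene_id = rownames(out$surv$expression),
                           out$surv$expression, check.names = FALSE),
                fp("survival_expression.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(out$truth, fp("truth.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  out
}
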