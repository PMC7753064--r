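#' Pipeline run configuration
#'
#' Paths to the stage inputs plus the analysis thresholds, echoed into the
#' run manifest. Thresholds default to the values used throughout the
#' package: 200-bp bins, +/-2 kb promoters, |log2FC| cutoff 1, p cutoff
#' 0.05, closeness cutoff 130, top 30% of overexpressed genes by degree,
#' kappa cutoff 0.4.
#'
#' @param input_dir directory holding the input files (the layout written
#'   by \code{\link{simulate_study}}).
#' @param out_dir output directory for stage artifacts and the manifest.
#' @param seed integer seed echoed into the manifest.
#' @param bin_size,flank,fc_threshold,p_threshold,closeness_min,top_frac,kappa_threshold
#'   stage thresholds.
#' @param from_state,to_state transition whose promoter genes are extracted.
#' @param genome_size genome length used by the co-localization test;
#'   \code{NULL} derives it from the segmentation span.
#' @return list with class \code{"run_config"}.
#' @export
run_config <- function(input_dir, out_dir, seed = 1,
                       bin_size = 200, flank = 2000, fc_threshold = 1.0,
                       p_threshold = 0.05, closeness_min = 130,
                       top_frac = 0.30, kappa_threshold = 0.4,
                       from_state = "E4", to_state = "E1",
                       genome_size = NULL) {
  stopifnot(bin_size >= 1, flank > 0, fc_threshold >= 0,
            p_threshold > 0, p_threshold <= 1,
            top_frac > 0, top_frac <= 1)
  structure(as.list(environment()), class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes the stages in order -- chromatin-state transitions, interval
#' annotation and co-localization, mark/expression integration, PPI hub
#' screening, survival signature -- reading the plain-text inputs of
#' \code{input_dir} and writing every stage artifact plus a JSON manifest
#' (config echo, seed, md5 of each artifact) to \code{out_dir}. The run is
#' deterministic for fixed inputs and seed; any stage failure aborts with
#' the stage name.
#'
#' @param cfg \code{run_config}.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  ip <- function(f) {
    p <- file.path(cfg$input_dir, f)
    if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
    p
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  op <- function(f) file.path(cfg$out_dir, f)
  report <- list(seed = cfg$seed)

  ## stage 1: chromatin-state transitions
  res <- .stage("transitions", {
    seg_n <- read_bed(ip("seg_normal.bed"))
    seg_t <- read_bed(ip("seg_tumor.bed"))
    tn <- bin_segmentation(seg_n, cfg$bin_size)
    tt <- bin_segmentation(seg_t, cfg$bin_size)
    te <- normalized_enrichment(raw_enrichment(joint_occupancy(tn, tt)))
    write_transition_matrices(te, op("transitions"))
    chi <- chisq_independence(te)
    genes <- read_gene_models(ip("genes.tsv"))
    tg <- transition_genes(tn, tt, cfg$from_state, cfg$to_state, genes,
                           cfg$flank)
    writeLines(tg, op("transition_genes.txt"))
    nes <- te$nes; diag(nes) <- NA
    top <- which(nes == max(nes, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    list(te = te, chisq = chi, genes = genes,
         top_transition = list(from = te$states[top[1L]],
                               to = te$states[top[2L]],
                               nes = max(nes, na.rm = TRUE)),
         n_transition_genes = length(tg))
  })
  report$transitions <- list(chisq = res$chisq,
                             top_transition = res$top_transition,
                             n_transition_genes = res$n_transition_genes,
                             excluded_bins = res$te$n_excluded)
  genes <- res$genes

  ## stage 2: intervals -- feature annotation and mark co-localization
  alterations <- .stage("intervals", {
    alt <- read.delim(ip("mark_alterations.tsv"), stringsAsFactors = FALSE)
    ann <- feature_distribution(bed_intervals(alt$chrom, alt$start,
                                              alt$end), genes)
    write.table(ann, op("feature_distribution.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    by_mark <- split(alt, alt$mark)
    combos <- mark_combination_counts(lapply(by_mark, function(d)
      bed_intervals(d$chrom, d$start, d$end)))
    write.table(data.frame(combination = names(combos), bp = combos),
                op("mark_combinations.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    gsz <- if (is.null(cfg$genome_size))
      sum(tapply(alt$end, alt$chrom, max)) * 2 else cfg$genome_size
    pairs <- utils::combn(names(by_mark), 2L)
    fish <- apply(pairs, 2L, function(pr) {
      f <- fisher_colocalization(by_mark[[pr[1L]]], by_mark[[pr[2L]]], gsz)
      data.frame(mark_a = pr[1L], mark_b = pr[2L], p = f$p_two_tail)
    })
    write.table(do.call(rbind, fish), op("colocalization_fisher.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    alt
  })
  report$intervals <- list(n_alterations = nrow(alterations))

  ## stage 3: integration with expression
  integ <- .stage("integrate", {
    dmps <- read.delim(ip("dmps.tsv"), stringsAsFactors = FALSE)
    expr <- read_expression(ip("fpkm.tsv"), ip("pairing.tsv"))
    meth <- summarize_methylation(dmps)
    profiles <- build_gene_profiles(alterations, dmps, genes, cfg$flank)
    write.table(profiles, op("gene_profiles.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ae <- additive_effect(profiles, expr)
    write.table(ae, op("additive_effect.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    cand <- select_candidates(profiles, expr, cfg$fc_threshold,
                              cfg$p_threshold)
    write.table(cand$table, op("candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    mec <- methylation_expression_correlation(dmps, expr, genes, cfg$flank)
    list(meth = meth, profiles = profiles, cand = cand, mec = mec,
         expr = expr)
  })
  report$integrate <- list(
    n_dmps = integ$meth$n_total, frac_hypo = integ$meth$frac_hypo,
    cgi_chisq_p = integ$meth$chisq_yates$p,
    n_profiled = length(unique(integ$profiles$gene_id)),
    n_overexpressed = length(integ$cand$overexpressed),
    n_underexpressed = length(integ$cand$underexpressed),
    meth_expr_r = integ$mec$r_overall,
    meth_frac_negative = integ$mec$fraction_negative)

  ## stage 4: PPI hub screen
  hubs <- .stage("network", {
    edges <- read.delim(ip("ppi_edges.tsv"), stringsAsFactors = FALSE)
    cent <- centralities(edges)
    write.table(cent, op("centralities.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    h <- hub_filter(cent, integ$cand$overexpressed,
                    integ$cand$underexpressed, cfg$closeness_min,
                    cfg$top_frac)
    writeLines(h, op("hub_genes.txt"))
    h
  })
  report$network <- list(n_hubs = length(hubs))

  ## stage 5: survival signature
  surv <- .stage("survival", {
    clinical <- read.delim(ip("survival.tsv"), stringsAsFactors = FALSE)
    sexpr <- read.delim(ip("survival_expression.tsv"),
                        check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(sexpr[, -1L, drop = FALSE]); rownames(m) <- sexpr[[1L]]
    sd_ <- survival_data(clinical, m)
    cand_genes <- if (length(hubs)) hubs else
      head(sort(unique(integ$profiles$gene_id)), 20L)
    model <- suppressWarnings(
      build_signature(sd_, cand_genes, cfg$p_threshold))
    write.table(model$screen, op("signature_screen.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out <- list(model = model, n_signature = model$n)
    if (model$n > 0L) {
      grp <- dichotomize(sd_, model)
      write.table(data.frame(sample_id = names(grp$scores),
                             score = grp$scores,
                             group = ifelse(names(grp$scores) %in%
                                              grp$high_risk, "high", "low")),
                  op("risk_scores.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      hi <- sd_$clinical[sd_$clinical$sample_id %in% grp$high_risk, ]
      lo <- sd_$clinical[sd_$clinical$sample_id %in% grp$low_risk, ]
      km <- rbind(data.frame(group = "high", km_estimate(hi)),
                  data.frame(group = "low", km_estimate(lo)))
      write.table(km, op("km_curves.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      out$logrank <- logrank(hi, lo)
    }
    mk <- suppressWarnings(subtype_markers(sd_, cand_genes,
                                           p_threshold = cfg$p_threshold))
    write.table(mk, op("subtype_markers.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$n_markers <- nrow(mk)
    out
  })
  report$survival <- list(n_signature = surv$n_signature,
                          logrank = surv$logrank,
                          n_subtype_markers = surv$n_markers)

  ## manifest: config echo (thresholds only), seed, artifact checksums
  arts <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
  manifest <- list(
    package = "epishift",
    config = cfg[setdiff(names(cfg), c("input_dir", "out_dir"))],
    report = report,
    artifacts = lapply(setNames(arts, arts), function(f)
      unname(tools::md5sum(file.path(cfg$out_dir, f)))))
  jsonlite::write_json(manifest, op("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
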