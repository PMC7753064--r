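# epishift

Downstream analysis of paired tumor/normal epigenome profiling in R.

After segmentation tools, differential-region callers and expression
quantification have done their work, a typical cancer-epigenome study still
needs a set of bespoke computations to tie the pieces together. `epishift`
implements that layer as tested, reusable functions:

- **Chromatin-state transition enrichment.** Two genome segmentations
  (e.g. a 19-state ChromHMM-style vocabulary for normal and tumor tissue)
  are projected onto 200-bp bins and their joint state occupancy is scored
  against an independence null. For normal state *i* and tumor state *j*,

  RES(i,j) = N_observed(i,j) / N_expected(i,j),
  NES(i,j) = RES(i,j) / RES(j,i),

  where N_expected is the product of the marginals over the co-covered
  bins. NES > 1 flags a directional state shift (say, weak TSS to active
  TSS); Pearson's chi-square tests overall independence, and the genes
  whose ±2 kb promoters harbor a chosen transition are extracted.

- **Genomic-interval engine.** BED-convention interval tables with
  intersection, bp-exact mark-combination partitioning, interval
  co-localization significance (two-tailed Fisher exact test on an
  overlap contingency table), and single-valued feature annotation
  (promoter <1 kb / 1–2 kb, UTRs, first/other exon and intron, downstream,
  distal intergenic) with promoter-first priority at the interval midpoint.

- **Combinatorial mark/expression integration.** Per-gene profiles of
  which of the six marks (H3K4me1, H3K4me3, H3K27ac, H3K27me3, H3K36me3,
  DNA methylation) are altered in the promoter and in which direction;
  classification into active / poised / repressive subgroups by the voting
  rule (active marks up and repressive marks down vote "activating");
  additive-effect analysis of mean log2 FPKM fold change by the number of
  altered marks; candidate retention (|log2FC| > 1, paired t-test
  p < 0.05); methylation–expression correlation; hypo/hyper × CpG-island
  chi-square with Yates correction.

- **PPI hub screening.** Degree and harmonic closeness centralities, the
  hub filter (closeness > 130, all underexpressed plus top 30% of
  overexpressed candidates by degree), Cohen's kappa between gene-set
  terms with component-based term grouping, and a generic hypergeometric
  over-representation test.

- **Survival signature.** Univariate Cox screening (Breslow ties), the
  risk score `sum(beta_i * Exp_i)` over the significant genes, median
  dichotomization into high/low risk, Kaplan–Meier curves, the log-rank
  test, and subtype-stratified (CIN / GS / EBV / MSI) classification of
  markers as Risky (beta > 0) or Protective (beta < 0).

- **Synthetic data with planted truth.** `sim_config()` /
  `simulate_study()` generate every pipeline input — segmentations with
  planted state transitions, promoter mark alterations with configurable
  co-localization and per-mark expression effects, CGI-biased methylation,
  paired FPKM tables, a scale-free PPI graph with forced hubs, and a
  survival cohort with planted per-subtype hazards — plus ground-truth
  sidecars, so every stage can be validated end to end.

## Worked example

```r
library(epishift)

cfg <- sim_config(seed = 1)            # 400 genes, 19 states, E4->E1 planted
sim <- simulate_study(cfg, out_dir = "sim")

m <- run_pipeline(run_config("sim", "run", seed = 1))
m$report$transitions$top_transition
#> $from
#> [1] "E4"
#> $to
#> [1] "E1"
#> $nes
#> [1] 84.27968
```

The planted weak-TSS-to-active-TSS rewrite (30% of E4 bins) is recovered
as the top-ranked off-diagonal NES. Downstream, the same run reports
(`m$report$integrate`, `$network`, `$survival`): 64 overexpressed and 67
underexpressed candidate genes, 46 hub genes after the closeness/degree
screen, a 4-gene survival signature whose high/low-risk split separates
survival at log-rank p = 9.7e-24, and 18 subtype-stratified prognostic
markers. The group-3 active subgroup shows a mean log2 fold change of
1.50 — three co-localized marks at +0.5 log2 each, the additive effect the
integration stage is designed to expose.

Every stage writes plain TSV/BED/JSON artifacts under the output
directory, together with `manifest.json` (config echo, seed, md5 per
artifact); reruns under the same seed are byte-identical. A thin CLI
wrapper with `simulate`, `run-all` and `transitions` subcommands is
installed under `inst/scripts/epishift`.

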