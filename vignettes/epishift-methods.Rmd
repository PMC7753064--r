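---
title: "Methods: chromatin-state transitions, combinatorial marks, and survival signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-state transitions, combinatorial marks, and survival signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`epishift` covers the downstream layer of a paired tumor/normal epigenome
study: everything that happens after segmentations, differential regions,
methylation calls and FPKM tables exist, and before biological
interpretation. This vignette documents the models, the parameters that
matter, the numerical conventions, and what the synthetic-data generator
does and does not emulate.

## Coordinates and containers

All genomic coordinates are BED convention — 0-based, half-open — because
that is what segmentation tools and differential-region callers emit.
Intervals are plain data frames (`chrom`, `start`, `end`, optional
`strand`, `payload`); interval arithmetic is delegated to
GenomicRanges/IRanges internally (with the one-off +1 shift at the
boundary), graphs to igraph, and survival model fitting to the survival
package. The package's own contributions — the enrichment scores, the
voting classification, the additive-effect analysis, the hub filter, the
risk score — are implemented here directly.

## Chromatin-state transition enrichment

Two segmentations are projected onto a fixed grid of `bin_size = 200` bp,
the resolution at which HMM-based segmentation tools emit states. A bin
straddling a state boundary takes the state covering the majority of its
covered bases, with ties going to the state found leftmost in the bin;
since real segmentations come in 200-bp multiples this rule exists mainly
for robustness to hand-edited inputs. Bins covered in only one track are
excluded from all totals (not imputed) and their count is reported.

With `observed[i, j]` the number of bins labeled state *i* in the normal
track and *j* in the tumor track, the null model is independence of the
two labels, so `expected[i, j] = n_i * m_j / N` over the N co-covered
bins. The raw enrichment score is `RES = observed / expected`; the
normalized score `NES[i, j] = RES[i, j] / RES[j, i]` measures directional
preference and satisfies `NES[i, j] * NES[j, i] = 1` wherever defined.
Entries whose denominator is zero are flagged `NA`, never infinite, so
that rankings simply skip them — an undefined direction is evidence of an
absent reverse transition, not of an infinitely strong forward one.
Enrichment is computed on the pooled pair of tracks; a per-sample variant
(compute per patient, then average) would need multiple segmentations per
condition and is left out of scope.

Pearson's chi-square on the observed matrix (all-zero rows/columns
dropped) tests overall independence. Genes "harboring" a transition are
those whose ±2 kb promoter contains at least one bin with the queried
(from, to) assignment.

## Interval co-localization and feature annotation

`fisher_colocalization` mirrors the interval-overlap Fisher test familiar
from BED toolkits: the 2×2 table counts a-intervals overlapping b,
a-intervals not overlapping, b-intervals not overlapping, and an estimate
of genome slots carrying neither, `floor(genome_size /
(mean_len(a) + mean_len(b)))` minus the other cells. That last cell is a
model, not a measurement — the tool convention this follows estimates how
many non-overlapping placements the genome could hold — and it is
documented here because the choice affects the p-value scale, not the
ranking of mark pairs.

Feature annotation assigns exactly one of ten categories, judged at the
interval midpoint so that intervals spanning boundaries stay
single-valued. The priority is promoter-first — Promoter(<1 kb) >
Promoter(1–2 kb) > UTR5 > UTR3 > FirstExon > OtherExon > FirstIntron >
OtherIntron > Downstream (≤3 kb past the gene end) > DistalIntergenic —
matching common annotator defaults; the promoter categories measure
unsigned midpoint-to-TSS distance, while the ±2 kb promoter *window* used
everywhere else is the symmetric interval around the TSS. Both feature
fractions are reported, per-region (default) and per-bp, since either
normalization is defensible for "percentage of alterations in feature X".
Ties between genes offering the same category go to the nearest TSS, then
lexicographic gene id — deterministic and stable under input reordering.

## Mark integration and the additive-effect analysis

A gene's profile records, for each of the six marks (H3K4me1, H3K4me3,
H3K27ac, H3K27me3, H3K36me3, mC), whether an altered region (or, for mC, a
differentially methylated position) overlaps the ±2 kb promoter, and the
direction. For region marks the direction is the sign of the bp-weighted
sum of signed overlaps; for mC, bp-weighting is meaningless for point
CpGs, so the majority sign of promoter DMPs decides. Exact ties drop the
mark with a warning rather than guessing.

Classification is a voting rule: active marks (H3K4me1, H3K4me3, H3K27ac,
H3K36me3) up or repressive marks (H3K27me3, mC) down vote "activating";
the opposite votes "silencing"; unanimous profiles are active or
repressive, conflicting ones poised. The rule is order-free, so the
classification is permutation-invariant by construction.

Expression effects use per-gene `log2((mean tumor FPKM + 0.01) /
(mean normal FPKM + 0.01))`. The pseudocount 0.01 protects zero-FPKM genes
and is negligible for expressed ones (FPKM ≥ 1 shifts by < 0.015 log2
units). The additive-effect table groups genes by altered-mark count (1,
2, 3, 4+) and subgroup, reporting the mean fold change plus a paired
t-test on per-patient mean log2 expression. Candidate retention uses a
per-gene paired t-test across patients: the subgroup-level test says a set
of genes moved together, but retention is a per-gene decision, so the
per-gene test gates it (raw p, as thresholds are conventionally applied
at this step; BH-adjusted q is reported alongside). Retention requires at
least 3 patient pairs — below that a paired t-test is not meaningful.

The methylation–expression correlation is computed across genes (promoter
mean delta-beta vs log2 fold change). Across-samples-per-gene is the other
reading of "correlation between methylation and expression"; the
across-genes version is implemented because the inputs here are one
delta-beta summary per position, not per-sample beta values. The CDS scope
of the pairwise mark correlation is the union of exons minus UTR
intervals.

## Hub screening

Closeness here is the *harmonic* centrality, `sum over reachable v of
1/d(u, v)` — unbounded, growing with network size, the variant under which
a threshold like 130 is meaningful for networks of a few hundred nodes
(the normalized [0, 1] closeness could never exceed 1). The threshold is a
configuration knob (`closeness_min`, default 130, strict `>`). The screen
keeps all underexpressed candidates and the top `ceiling(0.30 * n)`
overexpressed candidates by degree (ties by closeness, then id), the
asymmetry reflecting that overexpressed candidates typically far outnumber
underexpressed ones. Candidate filtering happens before centrality
thresholding in `hub_filter`; callers wanting the other order can
pre-filter the centrality table. Kappa-based term grouping uses connected
components of the kappa ≥ 0.4 term graph — simpler than iterative
merging heuristics and deterministic, at the cost of chaining loosely
linked terms into one group.

## Survival signature

Univariate Cox fits use the Breslow tie approximation (ties are frequent
in discretized survival data), convergence tolerance 1e-8, at most 50
Newton iterations; degenerate genes (fewer than 2 events, zero variance,
non-convergence) are flagged and skipped rather than poisoning the
screen. Screening keeps Wald p < 0.05; the Wald test matches common
practice for univariate signatures. The risk score is the exact linear
combination of the signature genes' expression weighted by their Cox
coefficients; the median splits patients with ties going to low-risk, so
group sizes differ by at most 1 for distinct scores. Subtype-stratified
marker tables refit the univariate model per subtype (ALL, CIN, GS, EBV,
MSI) — refitting, rather than reusing ALL-cohort coefficients, is what
gives subtype-specific survival curves their coefficients; a gene is
Risky when higher expression associates with worse survival (β > 0),
Protective otherwise.

## What the generator emulates — and what it does not

`sim_config()` defaults are the study conditions the package is tested
under: a two-chromosome 6-Mb genome, 400 non-overlapping genes, the
19-state vocabulary with one planted transition (30% of E4 bins rewritten
to E1), a 5% background state-discordance rate (without it the reverse of
the planted transition would never occur and its NES would be undefined —
real segmentation pairs always disagree somewhere), ±0.5 log2 expression
effect per altered promoter mark, 19 matched tumor/normal pairs (the size
of the cohort this class of study profiles), hypermethylated positions
flagged CpG-island at rate 0.9, a 400-patient survival cohort with ~30%
censoring and planted log-hazards of 1.0. Genes are spaced ≥4 kb apart so
that a planted promoter alteration is attributable to exactly one gene —
the recovery tests depend on that, and real promoter interference is
deliberately out of scope.

Noise is Gaussian (expression, log2 scale, sd 0.5/sample) or exponential
(survival); generation is byte-identical under a fixed seed, with each
generator drawing from its own derived sub-seed so outputs do not depend
on call order. Ground truth (per-gene marks, votes, planted effects,
rewritten bin counts, hazard plants, forced hubs) is emitted alongside.

Not emulated: raw reads, array beta-value noise models, batch effects,
copy-number confounding, overlapping genes, inter-patient heterogeneity of
mark effects, and correlated censoring. Passing recovery tests on this
generator demonstrates the computations are correct and calibrated under
their stated assumptions — not that those assumptions hold in any given
real cohort.

## Test problem sizes

The suite validates RES/NES against per-base brute-force recomputation on
≤10-kb toy genomes; chi-square null calibration over 200 replicate pairs
of 1000-bin i.i.d. tracks (rejection at α = 0.05 within the binomial 99%
interval); the subgroup rule against an independent restatement over all
3^6 − 1 direction assignments; additive-effect recovery at 1500 genes and
null false-retention over 100 seeds of a 150-gene generator; Fisher/ORA
p-values against exact enumeration on all tables with total ≤ 30; Cox
coefficient recovery over 100 seeds at n = 300 (planted log HR 1.0); and
byte-identical manifests for repeated simulate-plus-run-all at a 90-gene
configuration. These sizes were chosen to give the statistical checks
adequate power while keeping the full suite comfortably fast.

## Known limitations

- The annotation priority order and the n22 slot estimate of the
  co-localization test are conventions, not estimands; comparisons across
  tools should fix them identically.
- NES is pooled-sample; per-patient NES with uncertainty would require
  replicate segmentations.
- The kappa grouping's connected components can chain distantly related
  terms through intermediates.
- The hub screen's closeness threshold is scale-dependent; on networks
  far from a few hundred nodes it should be re-derived, not reused.
- Cox screening is univariate by design; correlated signature genes will
  carry redundant coefficients into the risk score.
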