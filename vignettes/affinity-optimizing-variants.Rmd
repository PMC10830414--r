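---
title: "Scoring and testing affinity-optimizing enhancer variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and testing affinity-optimizing enhancer variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affopt)
```

## The model

Enhancers commonly work through transcription-factor binding sites whose
affinity is far below the optimal sequence for the factor — "suboptimal" or
"low-affinity" sites. Because such sites are plentiful and degenerate, a
single-nucleotide variant (SNV) that *raises* a site's affinity even modestly
can push an enhancer into ectopic, gain-of-function (GOF) expression. `affopt`
implements the analysis chain built around that idea:

1. **Relative affinity.** A protein binding microarray (PBM) measures a
   factor's binding signal for all 65,536 8-mers. Each 8-mer's *relative
   affinity* is its median intensity divided by the maximal median intensity,
   so the optimal 8-mer scores exactly 1.00 and a typical functional enhancer
   site sits in the 0.1–0.4 range. Lookups are strand symmetric: an 8-mer and
   its reverse complement always score the same (the maximum over the two
   orientations stored for the table).

2. **Motif scanning.** Binding-site families are described by length-8
   degenerate consensi over `A,C,G,T,N,W,K,M` — built-ins are ETS
   (`NNGGAWNN`), AP-1 (`NTKANNMA`) and IRF (`NWNNGANA`). A scan reports every
   8-base window matching the pattern on either strand, each with its
   relative affinity. Overlapping windows and both-strand matches are all
   reported; `merged_site_count()` provides the collapsed tally for
   comparison with site counts that merge overlaps.

3. **SNV classification.** For an SNV, all (up to) eight covering windows on
   both strands are scored before and after the substitution. Windows where
   both alleles match the pattern give a fold change (alt affinity / ref
   affinity). An SNV is *affinity-optimizing* when any such fold reaches the
   family threshold — 1.59× for ETS, 1.5× for AP-1/IRF — and *neutral in
   site* when every fold sits inside the 0.8–1.25× band. Alt-only matches are
   *de novo sites*, ref-only matches *site ablating*; both are kept distinct
   from optimization and fall into the "all other" analysis group. Folds
   strictly between the neutral band and the optimizing threshold match none
   of those definitions; we give them their own label,
   `affinity_subthreshold`, also grouped with "all other", so the three-way
   grouping used in the enrichment tests — optimizing / in-site-no-change /
   all-other — exactly partitions the SNV set.

4. **Enrichment testing.** MPRA variant-effect tables are joined to the
   classification; raw p-values are Benjamini–Hochberg adjusted (unless the
   study already published adjusted values, which are then used as-is), and
   each SNV gets a direction-signed −log10(p_adj). GOF means adjusted p
   strictly below α = 0.05 with increased expression. One-tailed
   Mann–Whitney U tests ask whether the optimizing group (and, as a negative
   control, the neutral group) is stochastically greater than the rest;
   Fisher's exact test and a fold-enrichment ratio compare GOF rates. eQTL
   tables follow the same path with Bonferroni adjustment over the full
   family of genotype–gene tests, the most significant gene kept per variant
   (ties: smaller raw p, then lexicographic gene label), direction from the
   sign of β, plus a stratified report over increasing fold cutoffs.

5. **Affinity–ChIP correlation.** Predicted sites are binned by affinity
   (0–0.1, …, 0.9–1.0; final bin closed), the mean per-base ChIP signal over
   each 8-base window is averaged per (bin, chromosome), and Spearman's rank
   correlation is taken over all points.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `opt_fold` | 1.59 (ETS), 1.5 (AP-1/IRF) | minimum alt/ref affinity fold for an optimizing call; a relaxed `> 1.0` rule suits sparse mutagenesis designs where almost no variant reaches 1.59 |
| `neutral_band` | [0.8, 1.25] | fold interval treated as "does not change affinity" (inclusive) |
| `alpha` | 0.05 | GOF significance level, strict inequality on adjusted p |
| `exact_limit` | 400 | MWU switches from exact enumeration to the tie/continuity-corrected normal approximation when `n_a * n_b` exceeds this (or any ties are present) |
| `loc_tol`, `aff_tol` | 0, 0.05 | conservation tolerances for pairing sites through a pairwise alignment: projected starts within `loc_tol` alignment columns and affinities within `aff_tol` |
| `floor` | 1e-300 | clamp applied to adjusted p before the log, preventing infinities |

## What the synthetic generator emulates

Every input class the pipeline consumes can be generated with known ground
truth (`generator_config()` and the `gen_*` functions):

* **PBM table** — affinity of an 8-mer is `decay^(mismatches to the
  consensus)`, minimised over strand. This guarantees a strand-symmetric
  table with a unique optimum and a geometric low-affinity tail reaching the
  0.1–0.4 territory where functional sites live. `affinity_decay` may also be
  a length-8 vector of per-position decays: the scalar model permits only
  three SNV fold values (decay, 1, 1/decay), whereas position-specific decays
  produce the graded fold spectrum needed to exercise stratified fold-cutoff
  analyses. Default decay 0.55: three mismatches give 0.166, matching the
  low end of observed functional sites.

* **Enhancer** — 360 bp of uniform background carrying six non-overlapping
  planted ETS windows with target affinities 0.15–0.39 (the suboptimal range
  seen in real enhancers). Background bases that happen to form motif
  matches are iteratively re-randomised until a scan recovers exactly the
  planted sites, so the scan truth is unambiguous. With these defaults the
  saturation SNV set (3 × 360 = 1080 variants) contains roughly 15
  affinity-optimizing SNVs — about the count seen in a real ~0.5 kb
  enhancer's mutagenesis — which gives the one-tailed MWU ample power at a
  one-standard-deviation planted shift.

* **MPRA / eQTL tables** — each SNV's true effect is a biological baseline
  `N(0, noise_sd)` plus, for optimizing SNVs drawn with probability
  `gof_fraction`, a planted positive shift; the *observed* effect is the
  mean of `n_replicates` measurements with error `N(0, rep_noise_sd)`, and
  the p-value is a two-sided z-test of that replicate mean. `effect_size` is
  expressed in units of the observed-effect standard deviation
  `sqrt(noise_sd^2 + rep_noise_sd^2 / n_replicates)`, so "+1 SD" means the
  planted group is shifted by one SD of the per-SNV observed effect.
  Generating p-values through an explicit replicate model (rather than
  drawing them directly) means the BH step sees realistic dependence. With
  `effect_size = 0` all SNVs are exchangeable, which is what makes the null
  calibration of the group comparison well-posed even though individual
  p-values are not uniform (they carry genuine baseline variability, as real
  MPRA p-values do).

* **Signal track** — per-base signal over each site window is a monotone
  link of the site affinity plus Gaussian noise, written as bedGraph.

What passing these tests does *not* show: the generator has no barcode-level
MPRA counts, no sequencing error, no linkage disequilibrium among variants,
no correlated replicate structure, and its background sequence is uniform
rather than genomic. Results on real data additionally depend on the quality
of the published effect estimates and on the PBM table actually matching the
factor bound in vivo.

## Numerical and design choices

* **Coordinates.** Internally 1-based closed, the R/Bioconductor (IRanges)
  convention; BED output is converted to 0-based half-open and VCF input is
  1-based as the format requires. Reference-allele checks on variant
  application turn coordinate-convention mistakes into immediate, position-
  labelled errors.
* **Strand handling.** Tables collapse strands at lookup (max over the two
  orientations) rather than at load, so files whose two orientation columns
  disagree remain usable; the disagreement is logged.
* **Normalisation basis.** The median-intensity column, not the E-score, is
  normalised; column selection is configurable for other file dialects.
  Non-positive intensities are dropped before normalisation — a relative
  affinity must be a positive fraction.
* **MWU comparison variable.** The grouped comparisons run on the
  direction-signed −log10(p_adj) metric (the quantity the class-wise box
  plots display); raw effect sizes are available via `mwu_variable =
  "effect"`. Exactness switches to the normal approximation at
  `n_a * n_b > 400` or in the presence of ties, and the method used is
  recorded in the result.
* **Exact ρ = 1.** With several chromosomes contributing points to the same
  affinity bin, the bin midpoints tie while the per-chromosome means differ,
  so average-rank Spearman is necessarily below 1 even for a perfect
  monotone link. The zero-noise ρ = 1 check therefore uses a
  single-chromosome configuration; multi-chromosome runs are tested against
  the ρ ≥ 0.8 bound under noise.
* **Degenerate inputs.** Empty PBM tables, all-zero margins, unknown 8-mers,
  reference mismatches and constant signal tracks raise explicit errors (or
  NA-with-warning where a statistic is genuinely undefined) rather than
  returning silent zeros.
* **Problem sizes.** The shipped tests run the full pipeline at the default
  generator scale (1080-SNV saturation sets), 2,000 replicate draws for the
  null calibration of the group test, 100 generator seeds per arm for
  parameter recovery, and 500 sites for the affinity–signal correlation —
  desk-scale versions of the corresponding real-data analyses.

## Known limitations

* Only substitutions are modelled; indels, MNVs and haplotypes are out of
  scope, as is computing alignments (conservation mapping consumes a given
  pairwise alignment).
* k = 8 is fixed; factors whose cores are poorly captured by an 8-mer
  pattern need a user-supplied consensus and PBM table.
* The ChIP stage takes the signal track as given — no peak calling,
  normalisation or input correction.
* The eQTL stage consumes published association statistics; it does not fit
  eQTL models or handle linkage disequilibrium.
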