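# affopt — affinity-optimizing enhancer variant analysis

Enhancers harbour most disease-associated variants, yet picking the causal
single-nucleotide variant (SNV) out of the surrounding sea of inert ones is
hard. A productive mechanistic filter is *binding-site affinity
optimization*: enhancers typically rely on transcription-factor binding
sites far below the factor's optimal sequence, and an SNV that raises such a
site's affinity — even from 0.15 to 0.24 of optimum — can unleash
gain-of-function (GOF) expression and, in developmental enhancers,
phenotypes such as polydactyly.

`affopt` is an R package for the full analysis chain around this idea. It is
aimed at regulatory-genomics analysts who have a PBM 8-mer table for a
factor, enhancer sequences, and published variant-effect tables (MPRA or
eQTL), and who want to ask: *are the affinity-optimizing SNVs in this
enhancer the ones driving expression gains?*

## What it computes

* **Relative affinity**: for an 8-mer *w* with PBM median intensity
  *I(w)*, the score *a(w) = I(w) / max I*, with strand symmetry
  *a(w) = a(revcomp(w))*; the optimal 8-mer scores exactly 1.00.
* **Motif scans**: every window matching a degenerate core — ETS
  `NNGGAWNN`, AP-1 `NTKANNMA`, IRF `NWNNGANA`, or any user pattern over
  `{A,C,G,T,N,W,K,M}` — on both strands, with affinities attached.
* **SNV classification**: per-SNV fold change *a(alt)/a(ref)* maximised
  over all covering windows; *affinity-optimizing* at ≥ 1.59× (ETS) or
  ≥ 1.5× (AP-1/IRF), *neutral-in-site* within 0.8–1.25×, with de-novo-site
  and site-ablating events tracked separately.
* **Enrichment**: one-tailed Mann–Whitney U on direction-signed
  −log10(adjusted p) comparing optimizing / neutral / other SNV groups;
  GOF rates (p_adj < 0.05, expression up), Fisher's exact test and fold
  enrichment; Benjamini–Hochberg adjustment for MPRA tables, Bonferroni
  (with the full family size) plus most-significant-gene selection for eQTL
  tables.
* **Affinity–ChIP correlation**: mean per-base signal over predicted site
  windows, averaged per (affinity decade bin × chromosome), Spearman-
  correlated against the bin ladder.
* **Synthetic data**: a generator producing PBM tables, enhancers with
  planted sites, saturation-mutagenesis MPRA tables, eQTL tables and signal
  tracks with known ground truth, so every stage is testable offline.

## Worked example

Score the classic low-affinity ETS site scenario — a 0.15-affinity site
whose SNV lifts it to 0.24 (a 1.6-fold optimization) — then run a full
synthetic MPRA enrichment:

```r
library(affopt)

tab <- pbm_table(c("AAGGAAAT", "AAGGAAGT", "CCGGAAGT"),
                 c(150, 240, 1000), tf_name = "ETS-1-like")
ets <- motif_pattern("ETS")

relative_affinity("AAGGAAAT", tab)
#> [1] 0.15

seq <- paste0("CCTTTAAT", "AAGGAAAT", "ACTACTAC")
eff <- classify_snv(variant_window_effects(seq, 15, "A", "G", ets, tab))
eff$ref_best_affinity; eff$alt_best_affinity; eff$best_fold; eff$label
#> 0.15   0.24   1.6   "affinity_optimizing"

cfg <- generator_config(seed = 1)
pbm <- gen_pbm_table(cfg)
enh <- gen_enhancer(cfg, ets, pbm)
mp  <- gen_mpra_table(cfg, enh, pbm, ets)
run_mpra_enrichment(setNames(enh$sequence, enh$sequence_id),
                    mp$associations, ets, pbm)
#> no adjusted-p column found; applying Benjamini-Hochberg to raw p
#> Enrichment report (ETS pattern, opt fold >= 1.59, alpha = 0.05)
#>   analysed SNVs: 1080 (optimizing 15 / in-site-no-change 30 / all-other 1035)
#>   MWU optimizing vs other:      p = 0.02218
#>   MWU no-change vs other:       p = 0.9277
#>   GOF rate: optimizing 0.267 vs all 0.103 (fold 2.59, Fisher p 0.05912)
```

Reading the report: the 15 SNVs that optimize a planted ETS site are
significantly enriched for expression gains (one-tailed Mann–Whitney
p = 0.022) while SNVs inside sites that do not change affinity show no
enrichment (p = 0.93) — the planted ground truth of this seed. Their GOF
rate (26.7%) is 2.6× the dataset-wide rate, the same fold-enrichment
arithmetic used to quantify how much affinity filtering concentrates causal
variants.

A command-line wrapper over the same functions ships in
`inst/scripts/affopt` (`scan`, `score-variants`, `mpra-enrich`,
`eqtl-enrich`, `chip-corr`, `simulate`).

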