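# paleoploid

Inference of ancient whole-genome duplication (WGD) and of what happened to
the duplicated genes afterwards.

Given chromosome-level gene annotations, proteomes and CDS for one or two
species, `paleoploid` detects the three classical WGD signatures and dates
the event against a speciation:

- **Homology**: all-vs-all protein search (external `blastp` or a built-in
  Smith–Waterman aligner) with e-value/top-N filtering.
- **Synteny**: collinear paralog blocks by optimal dynamic-programming
  chaining on gene-rank coordinates (≥ 5 anchors, `max_gap` 25, tandem-array
  collapsing), paralogous chromosome pairing by mutual best-hit enrichment,
  duplicate classification (WGD/segmental, tandem, proximal, dispersed,
  singleton), and shared-block quartets across two species.
- **Ks dating**: protein-guided codon alignments; synonymous distance by an
  exact inversion of a 61-codon HKY-type codon process (the classical K2P
  recipe over-corrects by >20% at Ks ≈ 1 and is kept as `method = "k2p"`);
  KDE/GMM peak finding and WGD-versus-speciation event ordering, where
  K<sub>s</sub><sup>paralog</sup> > K<sub>s</sub><sup>ortholog</sup> in both
  species ⟺ the WGD predates their divergence.
- **Duplication statistics**: duplicated-gene fractions, exact/Monte-Carlo
  permutation group comparisons, conserved (Hox-like) cluster scanning.
- **Ohnolog fates**: expression-based classification of syntenic ohnolog
  pairs into nonfunctionalized / neo-or-subfunctionalized / both-responsive /
  conserved (Student t on log2(FPKM+1), optional BH-FDR), plus up-regulation
  trends along an exposure gradient.
- **Metabolites**: deterministic NIPALS OPLS-DA with VIP
  (`mean(VIP²) = 1`), inclusive fold-change/VIP thresholds, compound-class
  shares.
- **Simulator**: a forward genome-evolution simulator (WGD → speciation →
  loss, tandem duplication, inversion, translocation; matched expression and
  metabolome generators) with full truth labels, used for calibration and
  testing throughout.

See `vignette("wgd-methods")` for the model, the Ks estimator derivation and
the known limitations.

## Worked example

Simulate a mid-sized WGD genome pair and run the full pipeline:

```r
library(paleoploid)

cfg <- sim_config(n_chromosomes = 4, genes_per_chromosome = 60, seed = 7)
rep <- run_wgd_pipeline(cfg, quiet = TRUE)
print(rep)
```

```
<wgd_report>
  data         ok
  homology     ok
  synteny      ok
  ks           ok
  fate         ok
  metabolome   ok
  blocks: A 7, B 7, ortho 26; 4 chromosome pairs (A); 4 shared quartets
  Ks modes: paralog A 0.81, paralog B 0.89, ortholog 0.62 -> WGD_BEFORE_DIVERGENCE
  fates: 7.30% nonfunctionalized, 16.76% neo/sub of 370 ohnolog genes
  metabolites: 71 up / 45 down (Q2 = 1.00); top up class acyl-carnitine (47.89%)
  seed 7 | 2026-10-02 05:54:35
```

Both paralog modes exceed the ortholog mode, so the duplication predates the
two species' divergence. The same stages are available piecewise; for
example, Ks for a handful of true ohnolog pairs:

```r
sim <- simulate_genome(cfg)
pa  <- subset(sim$truth$ohnolog_pairs, species == "A")[1:5, c("gene1", "gene2")]
pairs_ks(pa, sim$species$A$cds)[, c("gene1", "gene2", "S", "Sd", "ks", "ka", "saturated")]
```

```
# A tibble: 5 × 7
  gene1   gene2       S    Sd    ks    ka saturated
  <chr>   <chr>   <dbl> <dbl> <dbl> <dbl> <lgl>
1 g0001.1 g0001.2  154.  80.5 0.877 0.167 FALSE
2 g0002.1 g0002.2  150.  69.5 0.720 0.185 FALSE
3 g0004.1 g0004.2  155.  65   0.611 0.161 FALSE
4 g0005.1 g0005.2  154.  79.5 0.847 0.143 FALSE
5 g0006.1 g0006.2  153.  74.2 0.765 0.136 FALSE
```

Real data enter through `inputs =` (protein/CDS FASTA + gene-level GFF3 per
species) instead of a simulation config; `out_dir =` enables on-disk stage
caching and writes `report.json` / `report.txt`, deterministic apart from
the isolated timestamp field.

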