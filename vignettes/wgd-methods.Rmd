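---
title: "Methods: inferring whole-genome duplication and ohnolog fates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring whole-genome duplication and ohnolog fates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
# The full scenario takes minutes; this vignette is a methods document and is
# not evaluated at build time.
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The inference problem

An ancient whole-genome duplication (WGD) leaves three genomic signatures
that survive hundreds of millions of years of gene loss and rearrangement:

1. **Collinear paralog blocks** — runs of neighboring genes on one chromosome
   whose paralogs are also neighbors on another chromosome.
2. **Chromosome-scale pairing** — interchromosomal paralogs concentrate on
   specific chromosome pairs rather than spreading uniformly.
3. **A mode in the paralog age distribution** — synonymous divergence (Ks)
   between retained duplicate pairs ("ohnologs") clusters around the age of
   the single duplication event, while small-scale duplications accumulate
   continuously.

`paleoploid` implements each signature as a separate module, then dates the
event against a speciation by comparing the paralog Ks mode with the
ortholog Ks mode of a second lineage: a WGD shared by two species predates
their divergence exactly when both species' paralog modes exceed the
ortholog mode.

## Lineage geometry in the simulator

The forward simulator (`simulate_genome()`) encodes that geometry
explicitly. An ancestral genome is duplicated at divergence `wgd_ks`
(default 0.8 expected synonymous substitutions per synonymous site, split
evenly over the two ohnolog copies). A speciation at `speciation_ks` 0.6
then separates species A and B; species B evolves an extra
`second_lineage_extra_ks` 0.2 so its paralog mode sits near 1.0 while the
A–B ortholog mode sits near 0.6. Each ohnolog copy is retained with
probability 0.8; tandem duplicates, segment inversions and translocations
are layered on top so the synteny machinery faces realistic noise. Every
pair (ohnolog, ortholog, tandem) is emitted with truth labels, which is what
the calibration tests in `tests/testthat/` consume.

## Ks estimation: why the K2P recipe over-corrects

Counting follows the classical synonymous/non-synonymous site partition:
protein-guided codon alignment (Needleman–Wunsch on translated sequences,
BLOSUM62, affine gaps), then per-codon-path averaging of synonymous and
non-synonymous sites and differences. The textbook recipe applies a Kimura
two-parameter correction to the synonymous partition. On simulated data with
known divergence that recipe is badly biased upward (around +22% to +26% at
true Ks 0.8–1.0) for three reasons:

- Two-fold degenerate sites admit only synonymous *transitions*; they
  saturate on a binary alphabet, not the four-letter alphabet K2P assumes.
- At omega < 1 the multi-step codon paths that K2P implicitly weights
  equally are not equally likely.
- The synonymous-partition transition/transversion ratio overstates the
  underlying nucleotide kappa (two-fold sites contribute transitions only),
  so the correction is applied with the wrong kappa.

`estimate_ks(method = "codon")` (the default) therefore inverts the observed
proportion of synonymous differences through the exact transition
probabilities of a symmetric 61-codon HKY-type codon process: the rate
matrix is eigendecomposed (memoized on a rounded kappa/omega grid), kappa is
solved so the expected synonymous transition share matches the observed one,
and omega is iterated from Ka/Ks. On simulator output the mean bias is
within ±1.5% at Ks 0.2–1.0. The K2P recipe is retained as
`estimate_ks(method = "k2p")` for comparison. Saturated pairs are flagged
(`saturated`) rather than extrapolated, and alignments under 30 counted
codons carry `low_confidence`.

```{r}
aln <- codon_align(cds_a, cds_b)
estimate_ks(aln)           # exact codon-process inversion
estimate_ks(aln, "k2p")    # classical two-parameter correction
```

## Synteny: chaining and tandem arrays

Anchors are homologous gene pairs placed on gene-rank coordinates
(`add_ranks()`, `build_anchors()`). `detect_blocks()` chains anchors by
dynamic programming: strictly monotone in both genomes (same or inverted
orientation), per-side rank gaps of at most `max_gap = 25`, scored as
`anchor_score` per anchor minus `gap_penalty` per skipped rank, and a block
must contain at least `min_genes = 5` anchors — four collinear genes are
noise, five are evidence. The chain score is provably optimal; the test
suite checks it against a brute-force subset-enumeration oracle.

Tandem arrays need special handling because a run of near-identical
neighbors creates a fake "diagonal" self-synteny block and splinters real
blocks. Following the usual collinearity-tool convention, `build_anchors()`
collapses same-chromosome anchor pairs within `collapse_tandem = 1` rank
into arrays (connected components) and remaps each array onto one
representative — the member with the strongest homology outside the array —
and `detect_blocks()` additionally keeps only the best anchor among those
sharing a gene within `collapse_gap` ranks. Duplicates separated from their
parent by later inversions, and rare score ties, remain positionally
ambiguous; `classify_duplicates()` resolves what it can by rank distance
(tandem ≤ 1, proximal ≤ 10, dispersed otherwise) with block membership
taking precedence.

`pair_chromosomes()` declares a chromosome pair when each side's
interchromosomal best-hit count is enriched at least two-fold over a uniform
background in both directions — the chromosome-scale WGD signature.

## Dating and event ordering

`ks_peaks()` estimates modes on a Gaussian KDE over the window
0.01 ≤ Ks ≤ 5 (a Gaussian mixture on log Ks is available via
`method = "gmm"`), and `order_events()` compares paralog modes against the
ortholog mode with an ambiguity band `delta`: every paralog mode must exceed
the ortholog mode by more than `delta` for `WGD_BEFORE_DIVERGENCE`.

## Ohnolog fates and exposure response

`classify_fates()` works on the ohnolog pairs from syntenic blocks: a gene
unexpressed in every sample marks its pair `nonfunctionalized_member`;
significant differential expression (Student t on log2(FPKM + 1) versus the
control group, p < 0.05) in exactly one member marks `neo_sub`; in both,
`both_responsive`; otherwise `conserved`. Percentages are reported over the
ohnolog-gene denominator. `up_trend()` counts significantly up-regulated
genes along the exposure gradient L → M → H and reports strict monotonicity
plus a Mann–Kendall-style sign statistic.

## Metabolite calls

`fit_opls()` is a deterministic NIPALS OPLS-DA (log2, mean-center, one
predictive plus `n_ortho` orthogonal components; 7-fold cross-validated Q²).
VIP is computed over the predictive component, so `mean(vip(m)^2)` is exactly
1. `call_differential()` applies the inclusive thresholds fold change ≥ 2 or
≤ 0.5 *and* VIP ≥ 1 on raw-scale group-mean ratios, and `class_share()`
summarizes compound-class shares among regulated metabolites.

## Limitations

- **Uncorrected per-group t-tests.** With three exposure contrasts at
  p < 0.05 and no correction, a null ohnolog pair is falsely called
  `neo_sub` with probability about 2q(1−q), q = 1 − 0.95³ ≈ 0.14 — roughly
  24%. The `fdr = TRUE` option (Benjamini–Hochberg per contrast) drives the
  false-call rate below 1% but costs substantial recall at n = 3
  replicates. The default matches the plain-p convention; choose per your
  error budget.
- **Permutation Q² is a guard, not a test.** Under label permutation of
  group-free data, Q² ≤ 0 holds in roughly 92% of permutations at 12
  samples; the positive tail is cross-validation variance, not model signal.
- **Ks at omega ≈ 1 with indels.** When selection does not constrain the
  protein, protein-guided alignment degrades and Ks inherits a few percent
  of upward misalignment noise even though the estimator itself is
  calibrated.
- **Positionally ambiguous tandems.** Inversion-separated tandem duplicates
  are indistinguishable from dispersed duplicates by position alone.
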