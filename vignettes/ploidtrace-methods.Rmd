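---
title: "Methods: selection screens and WGD dating from transcriptome assemblies"
author: "ploidtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection screens and WGD dating from transcriptome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ploidtrace)
```

## What the package computes

`ploidtrace` is a desk-scale re-implementation of a classic
transcriptome-based molecular-evolution workflow for a set of closely
related species (its fixtures emulate three polyploid blueberry-like
transcriptomes, tagged `T1`, `T2`, `T3`):

1. **Coding regions.** Each assembled unigene is assigned a protein-coding
   interval, either from a supplied annotation hit table (database priority
   Nr > Swiss-Prot > KEGG > COG, hits kept at E < 1e-5) or, failing that,
   from a deterministic six-frame longest-ORF scan (minimum 150 nt).
   Unigenes with neither are dropped from all downstream stages.
2. **Gene families.** All-vs-all protein similarity (local alignment,
   BLOSUM62, affine gaps 11/1) forms a homology graph; edges require a
   Karlin–Altschul-style e-value proxy ≤ 1e-7. Markov clustering (MCL)
   partitions the graph into families, classified as shared single-copy
   (exactly one gene per species), shared multi-copy, partially shared, or
   species-specific, with family and gene counts per Venn region.
3. **Selection screen.** For each single-copy family, proteins are aligned,
   back-translated onto their CDS, and every ortholog pair is scored with
   the Nei–Gojobori (1986) counting method: per-codon synonymous site
   fractions, pathway-averaged difference counts, and Jukes–Cantor
   correction, giving Ka, Ks and Ka/Ks. Validity is checked with Fisher's
   exact test on the rounded site/difference table. Pairs with Ks ≤ 0.1
   (potential paralogs) or saturated rates are excluded; the rest are
   binned: Ka/Ks > 1 strong positive, 0.5–1 weak positive, 0.1–0.5
   neutral, < 0.1 purifying.
4. **Enrichment.** Annotation terms of the positively selected set are
   tested with the exact hypergeometric upper tail
   $P = 1-\sum_{i=0}^{m-1} \binom{M}{i}\binom{N-M}{n-i}\big/\binom{N}{n}$
   and Bonferroni-corrected over the tested terms (those with $m \ge 1$);
   significance is called on the corrected p at 0.05.
5. **Phylogeny.** Per-family codon alignments are concatenated into a
   supermatrix (missing taxa gap-filled); pairwise-deletion p-distances
   (or Jukes–Cantor) feed a Saitou–Nei neighbor-joining tree with
   column-resampling bootstrap (default 1000 replicates), branch lengths
   in substitutions per site.
6. **WGD dating.** Within each species, paralog pairs are all coding pairs
   with ≥ 40% nucleotide identity over ≥ 300 aligned bp. Their Ks values,
   filtered to (0, 2] to avoid saturation, are histogrammed at bandwidth
   0.03 and fitted with a k-component univariate Gaussian mixture by EM
   (default k = 3). Each fitted peak mean is converted to an age with
   $T = K_s / (2r)$, $r = 6.1\times10^{-9}$ synonymous substitutions per
   site per year (a plant-average rate). With the package's default peak
   positions (modal Ks ≈ 0.11, 0.53, 1.42) this yields ages of roughly
   9, 43 and 116 million years.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `evalue_annotation` | 1e-5 | — | hit-table cutoff for annotation-guided coding regions |
| `min_orf_nt` | 150 | nt | minimum ORF length for the heuristic fallback |
| `evalue_homology` | 1e-7 | — | homology-edge threshold (e-value proxy) |
| `inflation` | 2.0 | — | MCL granularity; higher splits families harder |
| `ks_min_ortholog` | 0.1 | subst/site | ortholog pairs must exceed this Ks (paralog guard) |
| `ks_max_paralog` | 2.0 | subst/site | paralog Ks saturation cap |
| `min_identity`, `min_aligned_nt` | 0.40, 300 | —, nt | paralog-pair detection rule |
| `bandwidth` | 0.03 | subst/site | Ks histogram bin width over (0, 2] (67 bins) |
| `mixture_k` | 3 | — | Gaussian components in the Ks mixture |
| `n_bootstrap` | 1000 | replicates | NJ bootstrap iterations |
| `rate` | 6.1e-9 | subst/site/yr | synonymous rate in T = Ks/2r |

Boundary conventions for the selection bins: a ratio of exactly 1 is weak
positive; exactly 0.5 or 0.1 is neutral; `Ka = 0` with applicable Ks is
kept as purifying (ratio 0) rather than dropped. Pairs are excluded when
Ks ≤ 0.1 or either rate saturates (observed proportion ≥ 3/4, where the
Jukes–Cantor log is undefined; flagged `NA`, never an exception).

## The synthetic-data generator

Every stage is exercised on generated data, so nothing requires external
databases. `generate_fixture()` plants:

* shared single-copy families: a random root CDS per family (uniform over
  the 61 sense codons, a fixed ATG start that is never mutated), each
  species copy evolved with `mutate_to_target()` at half the family's
  target (Ka, Ks) so each pair meets the full target approximately
  additively;
* shared multi-copy families (one extra within-species duplicate at
  Ka 0.05 / Ks 0.30, rotating species);
* species-specific singletons;
* within-species paralog pairs whose true Ks is drawn from a truncated
  three-component Gaussian mixture (defaults: means 0.1144, 0.5281,
  1.4347; sds 0.0678, 0.2294, 0.3103; weights 0.40/0.35/0.25 — weights
  are free parameters of the fixture since only peak positions and widths
  are constrained by the emulated study conditions) with Ka = 0.2 Ks,
  purifying-dominated so that even old duplicates stay detectable at the
  40%/300 bp rule;
* annotation terms with configurable background frequency, multiplied on
  the planted query set (genes of families with target Ka/Ks > 0.5).

`mutate_to_target()` inverts the Jukes–Cantor correction
($p = \tfrac34(1-e^{-4d/3})$) into per-site substitution probabilities and
applies them per codon position, weighting by the position's synonymous
site fraction and drawing replacements only from non-stop single-base
mutants, so generated CDS never contain internal stops. Truncation of the
Ks mixture is by rejection sampling, preserving within-interval component
shapes.

What the generator does **not** emulate: read-level errors and assembly
chimeras, indels (substitution-only evolution), codon-usage bias,
rate variation across sites, and gene-length variation within a fixture.
Passing tests therefore demonstrate correctness of the algorithms under
clean substitution-model conditions, not robustness to real assembly
artifacts.

## Numerical and design choices

* **NG86 rather than a likelihood codon model.** Deterministic, fully
  reproducible, and exactly testable against enumeration over all 61 sense
  codons and 3721 codon pairs. Known bias: pathway counting underestimates
  rates as within-codon multiple hits approach saturation — measured at
  roughly −17% relative at Ka = 1.5 on 2000-codon genes. Round-trip
  property tests therefore hold a ±15% relative tolerance (with a 0.005
  absolute floor for Poisson counting noise) below 1.0 and ±25% at
  targets ≥ 1; the selection classifier is unaffected in practice because
  its bins sit far from saturation.
* **Fractional Fisher tables.** Pathway-averaged Sd/Nd are fractional;
  they are rounded half-up to integers for the exact test, a fixed
  convention for determinism.
* **ORF heuristic in place of a trained coding-potential model.** The
  six-frame longest-ORF scan is a deterministic stand-in; the `source`
  field distinguishes `annotation` from `orf_heuristic`, so a real
  external prediction can be injected through the hit-table interface.
  Ties between equal-length ORFs prefer + strand, then lower frame, then
  smaller start. Codons containing N translate to `X`, which never counts
  as a stop.
* **E-value proxy.** True BLAST e-values depend on database size; the
  in-process proxy uses fixed Karlin–Altschul parameters with the product
  of the two sequence lengths as search space. The 1e-7 default carries
  the intent of the homology cutoff; absolute e-value fidelity is not a
  goal.
* **MCL on the raw similarity graph.** Ortholog/inparalog-specific edge
  reweighting is omitted; scores weight the walk directly, self-loops are
  set to each column's maximum, and clusters are read off as connected
  components of the converged matrix's support. Since random-walk flow
  never crosses between connected components, clustering is computed per
  component, which keeps the dense iteration small.
* **Guide tree for progressive alignment.** Average-linkage clustering on
  shared-k-mer distances (k = 3 for proteins, 6 for DNA) orders the
  profile merges. An agglomerative guide is used instead of a
  neighbor-joining guide because it is already rooted (NJ trees are
  unrooted and would need an extra rooting convention) and behaves
  identically on the 2–4 sequence families that dominate this workflow.
  Profile columns are scored by expected substitution score with affine
  gaps (Gotoh dynamic program, in C++).
* **NJ determinism.** Q-criterion ties are broken by the lexicographically
  smallest taxon-label pair; negative branch-length estimates are clamped
  to zero. Distances use pairwise deletion so concatenated supermatrices
  with missing taxa do not lose whole columns; saturated Jukes–Cantor
  distances are capped at 3 substitutions per site.
* **EM initialization and restarts.** Means start at evenly spaced sample
  quantiles with pooled sd; five seeded restarts (jittered after the
  first) guard against local optima, and a component sd collapsing below
  1e-4 discards that restart. The log-likelihood is asserted
  non-decreasing. The mixture is fitted on the raw Ks axis with no
  truncation correction, mirroring common Ks-peak practice; this biases
  the oldest peak's mean slightly downward (its right tail is cut at
  Ks = 2), an effect of a few hundredths at the default parameters.
* **Seeding.** A single master seed fans out to per-stage seeds through a
  fixed affine counter scheme, so stages rerun standalone reproduce the
  pipeline's stage results; all seeded code paths save and restore the
  caller's RNG state.

## Problem sizes in the shipped tests

The test and acceptance fixtures are sized for a laptop-class single CPU:
fixtures of 20–30 single-copy families at 150-codon genes (a few hundred
genes per run), Ks mixture fits on 5000 simulated values with 20
repetitions, 500 planted ortholog pairs of 1000 codons for the
classification screen, and bootstrap counts of 50–200 in tests (the
pipeline default remains 1000). These sizes give the recovery statistics
quoted in the tests comfortable margins while keeping the whole suite in
the minutes range.

## Known limitations

* Counts that depend on real sequencing depth, database versions and tens
  of thousands of unigenes (total family numbers, per-class ortholog
  counts) are structural outputs here, not reproductions of any published
  table.
* NG86 saturates above Ks ≈ 2; the paralog cap and the exclusion flags
  make this explicit rather than correcting for it.
* The mixture model assumes Gaussian peaks on the Ks axis; heavy-tailed
  or lognormal peak shapes, and SiZer-style significance of peaks, are out
  of scope.
* Orthology is graph-clustering only — no reciprocal-best-hit filtering,
  synteny, or tree reconciliation.
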