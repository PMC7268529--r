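# ploidtrace

Selection footprints and whole-genome-duplication (WGD) dating from
multi-species transcriptome assemblies.

`ploidtrace` is for evolutionary geneticists who have assembled transcript
sets (unigenes) from a few closely related species — typically non-model
polyploids such as blueberry, where full genomes are impractical — and want
the classic desk analysis chain: which transcripts code for protein, how
genes group into families across species, how the species relate, which
single-copy orthologs show selection, and how many rounds of genome
duplication the paralog age distribution records.

## The core models

* **Ka/Ks by NG86 counting.** For an aligned codon pair, each codon
  position contributes a synonymous site fraction (fraction of non-stop
  single-base mutants that preserve the amino acid); differences between
  codons are averaged over all minimal mutational pathways that avoid stop
  codons. With S, N the site totals and Sd, Nd the difference totals,

      Ka = JC(Nd / N),   Ks = JC(Sd / S),   JC(p) = -(3/4) ln(1 - 4p/3).

  Fisher's exact test on [[Sd, S−Sd], [Nd, N−Nd]] gates validity. Pairs
  with Ks ≤ 0.1 or saturated rates are excluded; the rest are binned:
  Ka/Ks > 1 strong positive, 0.5–1 weak positive, 0.1–0.5 neutral,
  < 0.1 purifying.
* **Gene families.** Local protein alignments (BLOSUM62, affine gaps)
  above an e-value-proxy threshold of 1e-7 form a homology graph,
  clustered by Markov clustering (expansion/inflation iteration); families
  are classed single-copy / multi-copy / partially shared /
  species-specific with Venn accounting of families and genes.
* **Phylogeny.** Concatenated single-copy codon alignments, pairwise
  p-distances (or Jukes–Cantor), Saitou–Nei neighbor joining, and
  column-resampling bootstrap supports.
* **Enrichment.** Exact hypergeometric upper tail
  `P = 1 − Σ_{i=0}^{m−1} C(M,i) C(N−M,n−i) / C(N,n)` with Bonferroni
  correction over the tested terms.
* **WGD dating.** Within-species paralog pairs (≥ 40% identity over
  ≥ 300 bp) give a Ks age distribution on (0, 2], histogrammed at
  bandwidth 0.03 and fitted with a 3-component Gaussian mixture by EM;
  each peak mean converts to an age by `T = Ks / (2r)` with
  `r = 6.1e-9` synonymous substitutions/site/year.

A synthetic-data module generates three-species transcript fixtures with
planted ortholog divergences, mixture-distributed paralog ages, and
enriched annotation terms, so the entire pipeline is testable offline.

## Worked example

Fit the three duplication peaks of a simulated paranome and date them:

```r
library(ploidtrace)
ks  <- simulate_ks_sample(default_paralog_mixture(), n = 5000, seed = 42)
fit <- em_fit(ks, k = 3, seed = 42)
print(fit)
```

```
Gaussian mixture fit on 5000 Ks values (k = 3, loglik -1813.97)
  weight     mu  sigma age_My
1 0.3903 0.1224 0.0611  10.03
2 0.3593 0.5411 0.2233  44.35
3 0.2503 1.4233 0.2732 116.67
```

Each row is one fitted duplication burst: its mixture weight (share of
retained paralog pairs), modal Ks (`mu`), peak width (`sigma`, broadening
with age as diploidization erodes old duplicates), and the implied age in
million years from `T = Ks/2r`. Three well-separated peaks near Ks 0.12,
0.54 and 1.42 read as a recent (~10 My), medium (~44 My) and ancient
(~117 My) WGD event.

The full pipeline on a generated fixture:

```r
fx  <- generate_fixture(fixture_config(n_shared_single_copy = 20,
         n_shared_multi_copy = 5, n_species_specific = 6,
         gene_length = 150, n_paralog_pairs = 30, seed = 11))
rep <- run_pipeline(pipeline_config(out_dir = "run1", seed = 5),
                    unigenes = fx$unigenes, annotation = fx$annotation)
print(rep)
```

```
ploidtrace run report
  coding_regions     in    278  out    278  removed      0
  gene_families      in    278  out    133  removed    145
  kaks_filter        in     60  out     55  removed      5
  enrichment         in     14  out      1  removed     13
  phylogeny          in     20  out     20  removed      0
  ks_filter_T1       in     28  out     27  removed      1
  ks_filter_T2       in     29  out     29  removed      0
  ks_filter_T3       in     30  out     29  removed      1
  wgd_fit            in     85  out     85  removed      0
```

Every filter stage balances (`in = out + removed`); the 278 unigenes
collapse into 133 families (matching the planted truth exactly on this
fixture), 60 single-copy ortholog pairs enter the Ka/Ks screen and 5 are
excluded by the Ks > 0.1 filter, and one planted annotation term comes out
significantly enriched in the positively selected set. Artifacts (TSV
tables, Venn JSON, Newick tree, Ks histogram, mixture-fit JSON) land in
`out_dir`. A thin command-line wrapper with `simulate` and `run-all`
subcommands is installed at `inst/scripts/ploidtrace.R`.

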