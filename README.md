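# subgenomics

Methylome calling and sub-genome dominance analysis for mesopolyploid
genomes.

Mesopolyploid Brassica genomes descend from a whole-genome triplication:
every ancestral gene once had three copies, one per sub-genome.
Fractionation since then has been *biased* — one sub-genome (LF, least
fractionated) kept more genes than the other two (MF1, MF2) — and among
gene triplets that survive in full, the LF copy tends to be the
highest expressed ("sub-genome dominance").  Methylation patterns,
gene-family expansion, and centromere positions complete the picture.
This package implements the statistical machinery for that style of
analysis, together with synthetic-data generators with known ground
truth, so every claim is testable end to end.

## What it computes

* **Methylation calling** — the bisulfite non-conversion rate $e$ is
  estimated from an unmethylated lambda spike-in; each cytosine with $k$
  methylated reads out of $n$ is tested with the exact binomial tail
  $p = P(X \ge k),\ X \sim \mathrm{Bin}(n, e)$, with Benjamini–Hochberg
  control of the false discovery rate (`estimate_nonconversion()`,
  `call_sites()`).
* **Methylome summaries** — per-context genome-wide levels, per-feature
  levels (promoter/exon/intron/…), strand-aware metagene profiles, and
  fixed-width genome tracks (`context_levels()`, `feature_levels()`,
  `metagene_profile()`, `binned_track()`).
* **Sub-genome dominance** — for each fully retained triplet, a
  $3 \times 4$ sub-genome $\times$ tissue table on the
  $\ln(\mathrm{FPKM}+1)$ scale is tested for interaction with Tukey's
  one-degree-of-freedom non-additivity statistic
  $F = \mathrm{SS}_{\mathrm{na}} / \big((\mathrm{SS}_{\mathrm{res}} -
  \mathrm{SS}_{\mathrm{na}})/5\big)$ on $(1,5)$ df; shares of
  highest-expressed copies are summarised among significant triplets
  (`dominance_test()`, `dominance_summary()`,
  `cumulative_dominance_curve()`).
* **Synteny and fractionation** — homology-hit filtering (E-value gate
  plus top-40%-of-best bit-score margin), collinear anchor chaining by
  dynamic programming in gene-order coordinates, overlap resolution,
  block-wise LF/MF1/MF2 labelling by retained-anchor fraction, retention
  statistics, and gene categorisation (`filter_hits()`,
  `chain_anchors()`, `assign_subgenomes()`, `retention_stats()`,
  `classify_genes()`).
* **Expression clustering** — average-linkage clustering of tissue
  profiles under the $1 - r$ correlation distance, and the fraction of
  triplets separated across clusters (`cluster_expression_profiles()`,
  `triplet_separation()`).
* **Gene-family expansion** — per-family Pearson chi-square against
  proportional species totals with Bonferroni correction
  (`family_expansion_test()`).
* **Centromere mapping** — in progeny of first-division-restitution
  gametes, heterozygosity decays from 1 at the centromere as
  $P_{\mathrm{het}}(d) = 1 - \tfrac{1}{3}(1 - e^{-3d})$ with map
  distance $d$; the smoothed per-marker heterozygosity peak localises
  the centromere (`heterozygosity_profile()`, `estimate_centromere()`).
* **Integration** — gene-body methylation, methylation-vs-expression
  bins, sub-genome methylation comparisons (Kruskal–Wallis), and the
  triplet expression/methylation correlation matrix with angular-order
  output (`gene_body_methylation()`, `methylation_expression_bins()`,
  `subgenome_methylation_comparison()`, `triplet_correlation()`).
* **Synthetic data** — generators for genomes and gene models, bisulfite
  counts with a lambda spike-in, biased fractionation with decoy
  homology hits, triplet expression tables, and FDR progeny genotypes,
  all parameterised by one seeded `sim_config()`.

Results are tibbles throughout; model-like objects follow broom
conventions (`tidy()`, `glance()`) and the main result types have
`ggplot2::autoplot()` methods.  See `vignette("methods")` (source in
`vignettes/methods.Rmd`) for the statistical details and derivations.

## Worked example

```r
library(subgenomics)

# a small synthetic study: genome, bisulfite counts, spike-in
cfg <- sim_config(seed = 42, n_ancestral_genes = 150L)
me <- simulate_methylome_counts(cfg, n_sites_per_context = 20000L)
e_hat <- estimate_nonconversion(me$lambda)$e
round(e_hat, 5)
#> [1] 0.00497

calls <- call_sites(me$sites, e_hat, per_context = TRUE)
context_levels(calls)
#> # A tibble: 3 × 4
#>   context n_tested n_methylated level_pct
#>   <chr>      <int>        <int>     <dbl>
#> 1 CG         19988        10863     54.3
#> 2 CHG        19992         1738      8.69
#> 3 CHH        19990          428      2.14

# biased fractionation of 4,000 ancestral genes and its retention
big <- sim_config(seed = 42, n_ancestral_genes = 4000L)
fr <- simulate_fractionation(big)
rs <- retention_stats(fr$syntelogs)
rs$retention
#> # A tibble: 3 × 3
#>   subgenome n_retained retention_pct
#>   <chr>          <int>         <dbl>
#> 1 LF              1994          49.8
#> 2 MF1             1411          35.3
#> 3 MF2             1183          29.6

# dominance among the fully retained triplets
trips <- simulate_expression_triplets(big, rs$triplets)
fit <- dominance_test(trips)
fit
#> Sub-genome dominance fit: 191 triplets
#> # A tibble: 1 × 6
#>   n_triplets n_significant lf_share mf1_share mf2_share alpha
#>        <int>         <int>    <dbl>     <dbl>     <dbl> <dbl>
#> 1        191             9    0.333     0.222     0.444  0.05

# centromere mapping from FDR progeny (truth: 400,000 bp)
pg <- simulate_fdr_progeny(sim_config(seed = 42, n_chromosomes = 1,
        n_ancestral_genes = 0L, meiosis = list(n_progeny = 200L)))
estimate_centromere(heterozygosity_profile(pg))
#> # A tibble: 1 × 7
#>   chrom centromere_bp interval_start_bp interval_end_bp peak_het n_markers flat
#>   <chr>         <dbl>             <int>           <int>    <dbl>     <int> <lgl>
#> 1 chr1         408164            346939          448980    0.947        50 FALSE
```

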