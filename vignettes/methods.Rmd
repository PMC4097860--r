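---
title: "Statistical methods behind subgenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind subgenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models, estimators, and numerical
conventions implemented by **subgenomics**, and the rationale for the
default parameters of its synthetic-data generators.  It is a methods
reference, not a tutorial; the README contains a worked end-to-end
example.

## 1. Binomial methylation calling with a spike-in control

A bisulfite experiment observes, at each cytosine, $k$ methylated reads
out of $n$.  Unmethylated cytosines can still read methylated because of
incomplete bisulfite conversion; the non-conversion rate $e$ is estimated
from reads aligned to an unmethylated spike-in (lambda phage) as the
pooled ratio

$$\hat e = \frac{\sum_i k_i^{(\lambda)}}{\sum_i n_i^{(\lambda)}},$$

implemented in `estimate_nonconversion()`.  Each genomic site with depth
$n \ge$ `min_depth` is then tested against the null that all of its
methylated reads are non-conversion artefacts:

$$p = P(X \ge k), \qquad X \sim \mathrm{Binomial}(n, \hat e),$$

computed as `pbinom(k - 1, n, e, lower.tail = FALSE)`.  P-values are
Benjamini–Hochberg corrected and a site is called methylated when
$q < \alpha$ (`call_sites()`).  The called set is therefore a p-value
threshold set: if a site is called, every site with a smaller p-value in
the same correction stratum is also called.

Correction can be joint across contexts or within each context
(`per_context = TRUE`).  The choice matters for *level estimation*: with
joint correction the very large CG discovery set raises the shared BH
threshold (to roughly $\alpha \cdot R / m$), admitting weak null sites —
for example a depth-2 site with one methylated read has
$p \approx 2\hat e$ — and the resulting false positives inflate the
low-truth CHH context most in relative terms.  Genome-wide context
levels are therefore computed from per-context-corrected calls, which
matches the per-context estimand.

Sequence context is assigned from the genome as CG, CHG, or CHH by
looking one and two bases 3$'$ of the cytosine (reverse complement on the
minus strand); truncated contexts at sequence ends fall through to CHH
(`assign_context()`).

## 2. Methylome summaries

`context_levels()` reports, per context, the fraction of tested sites
called methylated.  `feature_levels()` restricts the same fraction to
sites overlapping gene parts (promoter, UTRs, exons, introns, downstream);
a site overlapped by several features contributes to each.
`metagene_profile()` averages per-gene methylation over fixed-width flank
bins (default 20 upstream and 20 downstream bins of 100 bp) and 40
length-scaled body bins, flipping coordinates for minus-strand genes;
genes are equally weighted by default, with pooled counting as an option.
`binned_track()` produces fixed-width (default 500 kb) genome tracks.

## 3. Tukey one-degree-of-freedom test for sub-genome dominance

Expression of a fully retained triplet across four tissues forms an
unreplicated $3 \times 4$ table on the $y = \ln(\mathrm{FPKM} + 1)$
scale.  With no replication there is no pure error term, so interaction
is tested with Tukey's single-degree-of-freedom multiplicative
contrast.  With row effects $a_i = \bar y_{i\cdot} - \bar y$ and column
effects $b_j = \bar y_{\cdot j} - \bar y$,

$$N = \sum_{ij} y_{ij} a_i b_j, \qquad
\mathrm{SS}_{\mathrm{na}} = \frac{N^2}{\sum_i a_i^2 \sum_j b_j^2}, \qquad
F = \frac{\mathrm{SS}_{\mathrm{na}}}
         {(\mathrm{SS}_{\mathrm{res}} - \mathrm{SS}_{\mathrm{na}})/5}$$

on $(1, 5)$ degrees of freedom, where $\mathrm{SS}_{\mathrm{res}}$ is the
additive-model residual sum of squares.  Under normal additive errors the
test is exact; the acceptance suite verifies its empirical size at
$\alpha = 0.05$ over 10,000 null tables to within the 99% binomial
confidence interval.

Two numerical points are worth recording:

* **Degeneracy.**  Tables with zero row or column variance, or whose
  residual is entirely absorbed by the non-additivity term
  ($\mathrm{SS}_{\mathrm{res}} = \mathrm{SS}_{\mathrm{na}}$), return
  $p = 1$ with a `degenerate` flag.  An *exactly* multiplicative table
  $y_{ij} = (1 + u_i)(1 + v_j)$ is degenerate under this rule — its
  residual $r_{ij} = (u_i - \bar u)(v_j - \bar v)$ is proportional to
  $a_i b_j$ — so the statistic is reported as significant only when
  noise leaves a nonzero remainder.
* **Invariance.**  The statistic is invariant to a grand additive shift
  $y_{ij} \mapsto y_{ij} + c$, but *not* to separate row or column
  shifts: $N$ depends on the estimated effects, which such shifts
  change.  Only the grand-shift invariance is asserted.

`dominance_test()` applies the test per triplet and records the
sub-genome with the highest tissue-mean expression (ties broken
LF > MF1 > MF2 and flagged).  `dominance_summary()` reports, among
significant triplets, each sub-genome's share of highest-expressed
copies; `cumulative_dominance_curve()` tracks those shares along the
p-value ranking.

## 4. Expression clustering and triplet separation

`cluster_expression_profiles()` clusters per-gene tissue profiles by
average-linkage agglomeration on the distance $d = 1 - r$, where $r$ is
the Pearson correlation across tissues, cut to exactly $k$ clusters.
Zero-variance genes carry no profile shape and are removed first.  The
merge-height sequence is validated against a brute-force $O(n^3)$
re-implementation; ties in merge order are resolved by `stats::hclust`
and are measure-zero for continuous data.  `triplet_separation()` reports
the fraction of clustered triplet-member genes whose triplet does not
fall in a single cluster (and, secondarily, the fraction of such
triplets); it is 0 when triplet members share profiles and 1 when the
three member classes are forced into different clusters.

## 5. Synteny, chaining, and fractionation

`filter_hits()` keeps homology hits with E-value $\le 10^{-20}$ whose bit
score is within the top 40% margin of the per-query best
($\mathrm{bit} \ge 0.6 \cdot \mathrm{best}$); a per-query quantile
variant is selectable.  The E-value gate is applied before the margin, so
a high-scoring but high-E-value hit cannot set the margin.

`chain_anchors()` chains collinear anchors in gene-order coordinates by
dynamic programming, maximizing $\sum \mathrm{score} -
\mathrm{gap\_penalty} \cdot \sum \mathrm{gaps}$ with both index gaps
bounded by `max_gap_genes`; both orientations are searched and chains are
extracted best-first, each anchor used at most once.  Score ties are
broken toward *longer* chains — in the DP recurrence, in the final cell
choice, and in the orientation choice — so extraction is deterministic
and agrees with exhaustive enumeration even when a short high-scoring
fragment ties a longer chain.  `resolve_chain_overlaps()` removes a query
gene shared between chains from all but the strongest chain and
recomputes pruned scores.

`assign_subgenomes()` ranks, within each ancestral block, the (up to
three) chain copies by retained-anchor fraction; ranks 1–3 become LF,
MF1, MF2.  At the default study design — retention probabilities
$(0.50, 0.35, 0.30)$ and roughly 400 genes per block — the LF label is
statistically identifiable (LF–MF1 separation $\approx 4.4$ binomial SE
per block) while the MF1/MF2 sub-ordering swaps in roughly 6% of blocks
by sampling noise alone; validation therefore asserts near-perfect LF
identification and a realistic bound on full three-label accuracy.
`retention_stats()` reports per-sub-genome retention and the fully
retained triplet list; with independent retention the expected triplet
fraction is the product of the three probabilities (0.0525 at the
defaults).

## 6. Gene-family expansion

`family_expansion_test()` applies, per family, a Pearson chi-square test
of the observed per-species counts against expectations proportional to
genome-wide species totals (or equal shares), with Bonferroni correction
across families.  The expanded species is the largest positive Pearson
residual, reported only for families significant after correction;
families with any expected cell below 1 are flagged as unreliable for the
chi-square approximation.

## 7. Centromere mapping from half-tetrad progeny

Progeny of first-division-restitution (FDR) unreduced gametes inherit
both parental centromeres, so heterozygosity is 1 at the centromere and
decays with map distance as crossovers exchange distal arms.
`simulate_fdr_progeny()` implements the full tetrad model: chiasmata
arrive as a Poisson process on the genetic map (Haldane, no
interference), each exchanging the arm distal to the crossover between
one chromatid of each homolog, and the FDR gamete takes one chromatid
from each homolog.

Under this model the expected heterozygosity at map distance $d$ Morgans
from the centromere has the closed form

$$P_{\mathrm{het}}(d) = 1 - \tfrac{1}{3}\left(1 - e^{-3d}\right),$$

derived from a three-state Markov chain on the number of parental-allele
chromatids per homolog pair, with the number of chiasmata distal to the
marker $\sim \mathrm{Poisson}(2d)$.  The asymptote is the classical
half-tetrad value $2/3$, *not* the $1 - 2r(1 - r) \to 1/2$ one would
obtain by treating the two transmitted chromatids as independent: the two
chromatids of one meiosis share chiasmata, and the derivation (and the
simulation, which matches it to within Monte-Carlo error) accounts for
that dependence.

`heterozygosity_profile()` computes per-marker heterozygous fractions and
`estimate_centromere()` smooths them (running mean over a marker window,
optionally over a bp window) and reports the peak, a support interval
where smoothed heterozygosity stays within `support_drop` of the peak,
and a `flat` flag; plateau ties resolve to the run midpoint.

## 8. Synthetic-data generators as study conditions

The generator defaults are fixed study conditions, chosen once to emulate
a mesopolyploid Brassica leaf methylome and mapping population: mean
read depth 7.29 per strand; true methylation levels CG 0.55, CHG 0.09,
CHH 0.02; non-conversion 0.005; retention probabilities
$(0.50, 0.35, 0.30)$ over 24 ancestral blocks; 49 progeny scored at 50
markers on a 2-Morgan chromosome.  Validation asserts recovery of these
values at stated tolerances rather than tuning them to the assertions.

Per-site true methylation is all-or-none (Bernoulli at the context
level) by default, matching the binomial read model; a mosaic option
uses the level directly as the per-read probability.  Feature-level
overrides (`feature_meth_levels`) set class-specific truth for
promoter/body/downstream/intergenic or individual gene parts, enabling
recovery tests for metagene steps and intron/exon contrasts.  The
expression model is
$y_{ij} = \mu + G_i + T_j + \mathrm{GT}_{ij} + \varepsilon_{ij}$ on the
$\ln(\mathrm{FPKM}+1)$ scale with the interaction absent, multiplicative
($\lambda G_i T_j$ — the alternative the Tukey test is powered against),
or free, plus an optional additive LF shift; FPKM values are
$\max(e^y - 1, 0)$.  Every generator reseeds from the config seed plus a
fixed per-generator offset, so each output is reproducible regardless of
call order.

Problem sizes used in validation (e.g. $10^5$ sites per context, 10,000
ancestral genes, 100 centromere replicates, 200 oracle instances) are the
package's own choices, sized so that stated tolerances have comfortable
power on one CPU in well under the respective time budgets.

## 9. Input and output conventions

All coordinates are 1-based inclusive (GFF3 convention); the bedGraph
exporter converts to 0-based half-open at the boundary.  Files are UTF-8,
tab-separated, with `.` for missing values, and every writer emits a
provenance comment line.  Readers validate rather than clamp: coordinate
violations, count inconsistencies ($k > n$), and malformed strands are
hard errors.
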