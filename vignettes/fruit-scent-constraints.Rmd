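---
title: "Quantifying phylogenetic and developmental constraints on fruit scent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phylogenetic and developmental constraints on fruit scent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocsignal)
```

## The problem

Headspace sampling of fruits yields a wide table: rows are individual fruit
collections, columns are volatile organic compounds (VOCs), cells are
internal-standard-normalized amounts. Two evolutionary questions can be asked
of such tables across a community of species:

* **Phylogenetic constraint.** Do closely related species emit similar scent
  bouquets? If scent is largely inherited, species profiles should carry
  *phylogenetic signal* — more resemblance among relatives than expected by
  chance.
* **Developmental constraint.** Ripe fruits develop from unripe fruits. Is
  the chemistry of the ripe stage limited to the biosynthetic pathways
  already active in the unripe stage, even when the individual compounds
  change?

`vocsignal` implements both analyses end to end, plus generators that
produce data with exactly the structure the analyses assume, so every stage
is testable without field data.

## From raw table to species profiles

1. **Filtering** (`filter_compounds`). Four removal rules, each optional:
   compounds predominantly present in control (empty-chamber) samples
   (operationalized as control mean ≥ fruit mean — no numeric rule is
   standard, so the weakest defensible dominance criterion is used);
   compounds present in more than 90% of all samples (a volatile found in
   every species is more plausibly a contaminant); compounds confined to one
   species and under 25% of the dataset's samples; and compounds never
   exceeding 1% of any species' total emission. The rarity fraction is
   computed over all non-control samples of the dataset. Every removal is
   logged (compound, rule, statistic) to a machine-readable report.
   Filtering is idempotent: removing compounds can only increase the
   remaining compounds' shares, so no rule can fire on a second pass.
2. **Species means** (`species_means`). Mean amount per compound over the
   samples of each species, zeros included.
3. **Relative amounts** (`relative_amounts`). Each species row is divided by
   its total emission. Normalization happens *after* species averaging by
   default (mean absolute amounts, then one division per species); the
   alternative — normalize each sample, then average — is exposed as
   `normalize_first = TRUE` in `run_signal`, since either order is
   defensible when individuals vary in total emission.
4. **Class aggregation** (`aggregate_classes`). Compounds are grouped into
   seven biosynthetic classes (aliphatics, aromatics, C5-branched,
   terpenoids, nitrogen/sulfur, miscellaneous cyclic, unknown) in a fixed
   canonical order; sums preserve each row total exactly.

Missing cells in delimited input are read as 0 (absence): these tables are
occurrence-style exports, not missing-at-random measurements.

## Phylogenetic signal

Zero-inflated compositional profiles violate the multivariate-normal
assumptions of direct variance-partitioning statistics, so the pipeline
works in dissimilarity space: Bray–Curtis dissimilarities among species
profiles, classical PCoA, and the multivariate signal statistic
$K_{mult}$ on the scores. With $C$ the phylogenetic covariance
($C_{ij}$ = depth of the MRCA of tips $i$ and $j$),
$\hat A = (1'C^{-1}1)^{-1} 1'C^{-1}Y$ and $R = Y - 1\hat A$:

$$K_{mult} = \frac{\sum_{ij} R_{ij}^2 \,/\, \sum_{ij} (C^{-1/2}R)_{ij}^2}
  {(\mathrm{tr}\,C - N/(1'C^{-1}1))/(N-1)}$$

$K_{mult}=1$ is the Brownian-motion expectation; on a star phylogeny the
statistic is identically 1. A single column reduces it exactly to
Blomberg's K, which the test suite pins to the closed-form value
$101/96$ on a worked 3-tip tree.

Inference is by randomization: species rows of $Y$ are shuffled across tips
(equivalent to shuffling tip labels — the standard scheme for this
statistic, preserving the internal correlation of $Y$), the statistic is
recomputed, and $p = (1 + \#\{K_{perm} \ge K_{obs}\})/(1 + n_{perm})$.
The add-one rule keeps $p > 0$. Shuffling profiles before the PCoA or
scores after it gives the identical statistic, since a row permutation
commutes with the distance computation; the implementation shuffles scores.
Default `n_perm = 1000`; the seed is a required, logged part of the
configuration.

### Numerical choices

* $C^{-1}$ and $C^{-1/2}$ come from a symmetric eigendecomposition with a
  relative eigenvalue floor of $10^{-10}$. Polytomies never make $C$
  singular by themselves and are left unresolved; duplicated tips do, and
  are reported.
* PCoA drops negative eigenvalues (inevitable for the semimetric
  Bray–Curtis) without Cailliez/Lingoes correction — the scores of the
  positive axes are used as-is, and the full spectrum is returned so the
  discarded share can be inspected. Positive axes below $10^{-8}$ of the
  leading eigenvalue are also dropped. All surviving axes are passed to
  $K_{mult}$, with no truncation.
* A constant-data guard uses an exact column-range test: the GLS residual
  of a constant column picks up $\sim 10^{-28}$ of floating-point noise, so
  a sum-of-squares test would never fire.
* Pairs of all-zero profiles have undefined Bray–Curtis dissimilarity; they
  are set to 0 with a warning rather than propagating NaN.
* Hierarchical clustering (for tanglegram export against the phylogeny)
  sorts species lexicographically before agglomeration so ties in merge
  heights resolve deterministically. UPGMA is the default linkage; it is a
  configuration knob (`complete`, `single`, `ward`) rather than a constant,
  since no single linkage is canonical for scent dendrograms.

## Developmental constraints

For species with both ripeness stages, class-level profiles are paired
(`pair_ripe_unripe`), the unknown class is dropped from both stages
*without renormalizing* the remaining shares (the exclusion is small —
in the generator defaults it averages ~1% — and renormalizing would couple
the remaining classes), and per-class Spearman correlations with two-sided
t-approximation tests are computed (`spearman_by_class`; midranks for ties;
an exact permutation test is available via `test = "exact"` for small n).
A class constant across species in a stage has undefined rank correlation
and is reported as `NA`, excluded from the summary.

The summary statistic is the weighted mean coefficient,
$\sum_k w_k \rho_k / \sum_k w_k$ with $w_k$ the mean ripe relative amount
of class $k$. Weights are normalized by their own sum by default (they sum
to slightly under 1 after the unknown-class exclusion, so normalization
makes the summary a true weighted mean); `normalize_weights = FALSE`
reproduces the raw-share variant, which differs by well under 1% when the
unknown share is ~1%.

## The synthetic-data generators

The generators define the package's study conditions and are first-class,
tested code:

* `simulate_tree(n, seed)`: Yule trees rescaled to unit depth.
* `simulate_bm_traits(tree, p, sigma2, seed)`: columns drawn from
  $\mathcal{N}(0, \sigma^2 C)$; the Monte-Carlo covariance is checked
  against $C$ entrywise in the tests.
* `simulate_scent_table(config, tree)`: compounds get classes by the
  configured proportions; species carry a compound with probability
  $1 -$ `zero_inflation`; carried amounts are log-normal (right-skewed and
  strictly positive, like GC-MS peak areas); individuals multiply the
  species profile by log-normal noise. With a tree, per-compound
  log-amounts evolve under Brownian motion, injecting a phylogenetic
  signal; without one, species are independent (the null).
* `simulate_paired_ripe_unripe(config)`: class compositions for the two
  stages are linked by a Gaussian copula whose Pearson parameter is set by
  the closed-form Gaussian relation $r = 2\sin(\pi\rho_S/6)$, pinned
  exactly at $\pm 1$; within classes, ripe compound identities are
  resampled with probability `compound_turnover`, reproducing conserved
  class composition with high compound turnover.

Defaults mirror a tropical-community study: 30 species × 3 individuals, 60
compounds, class shares dominated by aliphatics/aromatics/terpenoids with a
1% unknown share, `zero_inflation = 0.6`, target ripe/unripe class
correlation 0.7 with turnover 0.8. Compositional normalization (each row is
divided by its total) slightly attenuates the realized rank correlation —
at a target of 0.70 the recovered mean is ≈ 0.67 — because the row total
depends on all classes; the closed-form calibration is kept, and the
recovery tests use the ±0.1 band this implies.

What the generators do **not** emulate: detection-limit censoring, between-
batch instrument drift, correlated compound co-occurrence within pathways
beyond the class totals, and non-Brownian trait evolution. Passing tests
therefore demonstrate the statistical machinery, not robustness to those
features of real tables.

## Problem sizes in the test suite

The distributional checks run at sizes chosen to make Monte-Carlo error
comfortably smaller than the tested bands: Brownian-motion recovery of
$K_{mult}$ uses 500 replicates on a 64-tip tree (band $1 \pm 0.1$); the
type-I-error check uses 500 signal-free datasets on 32 tips with 200
permutations each (band $0.05 \pm 0.02$; the attainable rejection rate of
the add-one rule at $\alpha = 0.05$ with 200 permutations is
$10/201 \approx 0.0498$); the ripe/unripe round trip uses 200 replicates of
30 species. The full suite runs in well under a minute apart from these
Monte-Carlo blocks.

## Limitations

* Reproducing published community studies requires their supplementary
  scent tables and a pruned angiosperm megatree; pruned-tree branch lengths
  depend on the megatree version, which shifts $K_{mult}$ point estimates
  by a few hundredths.
* $K_{mult}$ on PCoA scores inherits the information loss of dropping
  negative Bray–Curtis eigenvalues; the retained-variance share is reported
  so users can judge it.
* Polytomies are known to inflate type-I error of signal tests slightly;
  since the package's typical use asks whether signal is *absent*, this
  bias is conservative for that conclusion, and no resolution step is
  applied.
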