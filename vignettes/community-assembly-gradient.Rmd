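---
title: "Partitioning community assembly along environmental gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning community assembly along environmental gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package answers

Microbial communities sampled along a steep environmental gradient — the
motivating case is denitrifier guilds (the *nirK*- and *nirS*-bearing
nitrite reducers) in montane soils — differ from site to site. The package
asks *why*: how much of that pairwise turnover is driven by deterministic
niche selection, and how much by the stochastic side of assembly
(dispersal limitation, homogenizing dispersal, drift)? It then asks which
measured environmental drivers the deterministic part tracks, and whether
community turnover predicts an ecosystem function such as the potential
denitrification rate (PDR).

The analysis chain is: rarefaction → α-diversity (observed richness,
Chao1) → Bray–Curtis β-diversity, PCoA and permutation NPMANOVA → the
phylogenetic/taxonomic null models (NTI, βNTI, RC~bray~) and the
five-process partition → driver attribution (Spearman + FDR, stepwise
regression, partial Mantel, MRM, PCNM, PLS path modeling).

## The null-model machinery

**βMNTD and βNTI.** For a sample pair, the between-sample mean nearest
taxon distance is

$$\beta\mathrm{MNTD} = \tfrac12\Big[\sum_i f_i \min_j d(i,j) +
\sum_j f_j \min_i d(j,i)\Big],$$

with $d$ the cophenetic (patristic) distance and $f$ relative abundances
(abundance weighting is on by default; a presence/absence toggle is
provided). The null shuffles taxon labels across the cophenetic matrix of
the full regional pool (all taxa in the table); `scope = "pairwise"`
restricts the shuffle to the two samples' taxa. βNTI is the z-score of the
observed βMNTD in that null. The same shuffle yields the within-sample
NTI, with the sign flipped so clustering is positive.

Two properties of this null are worth knowing. First, because one shuffle
relabels *both* samples, shared taxa always contribute zero: βNTI measures
phylogenetic turnover *beyond* compositional overlap. An identical pair is
invariant under every shuffle, so its null has zero spread — such pairs
are flagged undefined (`NA`), reported, and excluded from the process
fractions, never silently numeric. Strongly negative βNTI instead arises
when samples hold *different but closely related* taxa, which is exactly
the homogeneous-selection signature. Second, for small pools the
Monte-Carlo null can be replaced by exhaustive enumeration of all label
permutations (`exact = TRUE`), giving the exact z-score the test suite
verifies against an independent brute-force oracle.

**RC~bray~.** The abundance-based Raup–Crick metric locates the observed
Bray–Curtis dissimilarity in a null in which each sample is reassembled
preserving its richness and total abundance: species identities are drawn
without replacement with probability proportional to regional occupancy,
then the remaining individuals are allocated multinomially by regional
relative abundance. `RC = 2\,[P(\mathrm{null} < \mathrm{obs}) +
\tfrac12 P(\mathrm{null} = \mathrm{obs})] - 1 \in [-1, 1]`; ties count at
half weight because the classification thresholds are sharp but the
Methods-style definition gives no tie rule. Monte-Carlo mode draws a bank
of seeded null assemblies per sample and pairs the k-th draws of two
banks; each pair's null distribution is therefore exact marginally (draws
for the two samples are independent), while reuse across pairs only
induces between-pair correlation, which the partition does not use.
`exact = TRUE` enumerates every richness/abundance-preserving assembly
with its probability (tiny pools only).

**The five-process partition.** Pairs are classified by the standard
thresholds: βNTI > 2 heterogeneous selection; βNTI < −2 homogeneous
selection; |βNTI| < 2 with RC > 0.95 dispersal limitation, with
RC < −0.95 homogenizing dispersal, otherwise undominated. Boundary values
(βNTI exactly ±2, |RC| exactly 0.95) follow the strict inequalities and
fall to the stochastic/undominated side; ties are possible in principle,
so the convention is documented rather than implicit. Fractions are taken
over classified pairs and sum to one exactly.

The mean NTI is reported with a two-sided one-sample t-test against zero
as its significance summary (the choice of test is the package's own; the
per-sample NTI values are also returned so any other summary can be
applied).

## The synthetic gradient generator

Because the deposited field data are not required, every stage is
exercised against a generator whose regimes are *known*. Its defaults are
the study design the package emulates: 12 sites × 8 plots = 96 samples
from 1800–4100 m; MAT falling 0.67 °C and MAP rising 67.5 mm per 100 m;
pH spanning 3.53–7.23; sequencing depth 1500 (equal to the default
rarefaction depth). One top-level seed drives everything through a fixed
splitting rule, so identical scenarios reproduce byte-identically.

Mechanistically, expected abundance of taxon *i* in plot *j* is

$$E_{ij} \propto b_i \cdot
\exp\!\big(-s\,( \mathrm{trait}_i - \mathrm{env}_j)^2\big) \cdot
\exp\!\big(-\lambda\, d_{\mathrm{km}}(\mathrm{home}_i, j)\big) \cdot
\varepsilon_{ij},$$

followed by a multinomial draw to the fixed depth. The pieces:

* `b_i` — a fixed lognormal regional species-abundance distribution
  (`pool_sdlog`, default 1.5). Real amplicon tables are sparse and
  uneven; with a perfectly even pool every taxon occurs everywhere and
  βNTI degenerates (all pairs undefined), so unevenness is part of the
  realistic baseline, not a tuning knob.
* the Gaussian niche filter — `selection_strength` is the inverse squared
  niche width in units of the filtered variable (default 6 pH⁻²,
  i.e. a niche width of ≈0.3 pH units); `Inf` switches to a hard cutoff.
  Niche optima evolve by Brownian motion on a unit-depth Yule tree
  (`trait_sigma`, default 1 pH unit), which creates the phylogenetic
  conservatism the nearest-taxon statistics assume. The tree model is a
  deliberate simplification: the motivating studies infer gene trees from
  amplicons, which is out of scope here.
* the dispersal kernel — each taxon has a random home site and its
  immigration decays exponentially at `dispersal_decay` per km (default
  0 = well mixed; the dispersal-limited preset uses 1.5/km over ~2 km
  site spacing, i.e. a ≈95 % drop between neighbouring sites).
* drift — lognormal noise (`drift_intensity`) plus the finite-depth
  multinomial resampling.

Three presets name the canonical regimes: `"selection"` (strong conserved
filter, well mixed), `"dispersal_limited"` (no selection, strong decay),
and `"well_mixed"` (neither). On the full 96-sample design these recover,
respectively, heterogeneous selection as the modal process, a dominant
dispersal-limitation fraction, and a mostly
undominated/homogenizing-dispersal partition — which is what the
acceptance tests assert.

PDR is simulated as a fixed linear function of a weighted
community-composition score plus Gaussian noise, so that *composition*,
not total abundance, predicts the rate by construction. Note that a
distance-matrix regression of |ΔPDR| on Bray–Curtis is exactly linear
only when samples lie on a one-dimensional Bray–Curtis line (e.g.
two-taxon mixtures of equal totals, used as the exactness fixture); on
general tables the dependence is monotone and strong but not R² = 1.

**What the generator does not emulate:** PCR/sequencing error, chimeras,
compositional biases between guilds, genuinely non-Gaussian niches,
temporal dynamics, or co-occurrence structure within genomes. Passing
tests therefore demonstrate correctness of the statistics and the
qualitative behaviour of the regimes — not that any particular field
system is governed by them.

## Distance-matrix and path-model statistics

* Every permutation test uses the `(exceedances + 1)/(n_perm + 1)`
  convention with seeded, reproducible draws; exhaustive enumeration
  (small n) returns exact proportions instead.
* NPMANOVA permutes sample labels freely (no strata), matching a
  single-factor design; pairwise two-group tests are Bonferroni-adjusted.
* The Mantel statistic is Spearman by default (rank statistics are the
  package's default elsewhere too); Pearson by flag. The partial variant
  correlates the residuals of `dx|dz` and `dy|dz` — computed through the
  equivalent first-order partial-correlation identity, on ranks for the
  Spearman form. The conditioning matrix defaults to geographic distance
  in the pipeline. Mantel p-values are one-sided (upper tail), the
  community-ecology convention.
* MRM is OLS on the unfolded off-diagonal vectors; the permutation
  affects only the p-values, and coefficients are verified against direct
  OLS. Environmental variables are z-scored before Euclidean distances by
  default (`env_distance(standardize = TRUE)`), so drivers on different
  scales are comparable.
* PCNM axes come from the principal coordinates of the
  largest-MST-edge-truncated distance matrix (great-circle distances by
  default, planar for synthetic grids), positive-eigenvalue axes only.
* PLS-PM uses the classical defaults of the method: centroid inner
  scheme, mode A outer estimation, convergence at 1e-6 within 300
  iterations (non-convergence is an error with the iteration trace).
  Latent scores are standardized, so path coefficients are standardized
  OLS coefficients; GoF = √(mean communality × mean R²); indirect effects
  are products of path coefficients. The community block is encoded by
  the first two PCoA axes of the Bray–Curtis matrix — the design was
  open, and two axes keep the block faithful to the ordination actually
  examined; the number of axes is configurable.
* Stepwise regression is forward-only with an α-to-enter of 0.05
  (both-direction AIC by flag). Reported contributions are sequential
  (entry-order) shares of the total sum of squares — sequential rather
  than marginal because only sequential shares add up to the full-model
  R², which makes the table internally consistent.
* Chao1 is the bias-corrected form `S + F1(F1−1)/(2(F2+1))` (defined when
  F2 = 0); the classical form is a toggle. Rarefaction is a single seeded
  draw without replacement, samples below depth dropped with a warning.
* PCoA reports all eigenvalues, excludes negative ones from the
  variance-explained denominator, applies no correction, and flags their
  presence.

## Numerical and degenerate-input conventions

Undefined quantities are never silent numbers: zero-spread nulls (star
trees, identical pairs) flag NTI/βNTI as undefined; constant variables
flag Spearman and Mantel statistics; all-zero sample pairs are an error in
Bray–Curtis. Ties in permutation statistics are compared with a 1e-12
slack so exact-arithmetic ties count as exceedances. RC ties use an
absolute 1e-10 tolerance on Bray–Curtis equality.

## Problem sizes

The test suite runs the full machinery at the design scale it emulates
(96 samples × 150 taxa) with 199 null randomizations for the regime
checks, exhaustive enumeration for the exactness checks, and 200-replicate
calibrations for the type-I error of the permutation tests; these sizes
were chosen so the whole suite completes in a few minutes while keeping
every check at full design scale where the property is scale-sensitive.

## Known limitations

* The regional-pool null for βNTI conditions on the observed table; it
  does not model unseen taxa.
* RC Monte-Carlo mode shares null banks across pairs (see above); use
  `exact = TRUE` where enumeration is feasible if between-pair
  independence of the null draws matters.
* PLS-PM provides no bootstrap confidence intervals; path p-values are
  OLS t-tests on standardized scores.
* The generator's regimes are calibration devices for the statistics, not
  claims about any particular mountain's communities.

## A worked run

```{r example}
library(gradientAssembly)

sc <- scenario_preset("selection", seed = 101)
ds <- simulate_dataset(sc)
otu <- rarefy(ds$otu, depth = 1500, seed = 1)

cfg <- null_model_config(n_null = 199, seed = 7)
asm <- assembly_analysis(otu, ds$tree, cfg)
asm$partition          # five-process fractions
asm$mean_nti           # phylogenetic clustering summary

bc <- bray_curtis(otu)
permanova(bc, ds$metadata$site, n_perm = 999, seed = 2)
mantel_test(env_distance(ds$metadata, "pH"), bc,
            dz = env_distance(ds$metadata, c("latitude", "longitude"),
                              standardize = FALSE),
            n_perm = 999, seed = 3)
```
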