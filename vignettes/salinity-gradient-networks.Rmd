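---
title: "Microbial co-occurrence networks along salinity gradients: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbial co-occurrence networks along salinity gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

salinet studies how the complexity and stability of microbial association
networks respond to an environmental stress gradient — the motivating system
is river-to-sea transects where salinity rises from below 1 g/L to above
20 g/L — and how the *abundant* and *rare* biospheres divide the work of
holding those networks together. This vignette explains the models behind
each stage, the tunable parameters and their defaults, what the synthetic
community generator does and does not emulate, and the numerical choices a
user should know about.

## The analysis chain

The pipeline mirrors a standard amplicon survey workflow:

1. **Preparation** (`rarefy`, `classify_abundance`,
   `assign_salinity_groups`, `prevalence_filter`, `clr_transform`).
   Counts are rarefied to even depth by uniform subsampling without
   replacement. Taxa are assigned to biospheres by mean relative
   abundance: strictly above 0.1 % is *abundant*, strictly below 0.01 % is
   *rare*, everything else (including values numerically on a threshold)
   is *intermediate*. Classes are computed once on the full rarefied
   table, not per group, because the biosphere concept is a property of
   the whole community. Samples are sorted by salinity and chunked into
   equal consecutive groups (default six groups of eight); ties at a
   block boundary are broken by sample ID so the grouping is
   deterministic.
2. **Gradient statistics** (`geo_env_correlation`, `mantel_test`,
   `alpha_diversity`, `linear_trend`). Geographic distances are
   great-circle (haversine, mean Earth radius 6371 km). The Mantel test
   correlates the condensed upper triangles of two distance matrices and
   permutes rows and columns of the second jointly;
   `p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)` with 999 permutations by
   default. Community distance is Bray-Curtis on rarefied relative
   abundances; environmental distance is Euclidean on z-scored variables
   (the standardisation is our choice; the variables have heterogeneous
   units).
3. **Biomarker discovery** (`rank_biomarkers`, `select_biomarker_count`,
   `classify_colonizers`). A regression forest of taxon abundances
   against salinity is refit many times (default 1000 iterations of 500
   trees) and permutation importances are averaged. The biomarker count
   is chosen from a repeated cross-validated error curve (default
   10-fold, 5 repeats). "The error curve stabilised" is operationalised
   as the one-standard-error rule: the smallest count whose mean error is
   within one SE of the curve minimum. Biomarkers whose abundance falls
   (rises) significantly with salinity are low-salinity (high-salinity)
   colonizers; the rest are complex.
4. **Network construction** (`build_network`, `topology`,
   `powerlaw_fit`). Within one salinity group, taxa passing the
   prevalence rule (present in *all* of the group's samples by default;
   at least half reproduces the fungal variant) are CLR-transformed and
   correlated across the group's samples with Pearson's r. An edge is
   kept when `|r| >= threshold` with a uniform threshold of 0.96 (0.83
   for the fungal variant); both signs are kept and recorded. Isolated
   taxa are excluded from the node set. Topology reports node and link
   counts, average degree, average local clustering (nodes of degree < 2
   contribute 0), density, Krackhardt connectedness (share of node pairs
   joined by a path), greedy (CNM) modularity and module count, and the
   R-squared of the ordinary least-squares log-log fit to the unbinned
   degree-frequency pairs. Automatic random-matrix thresholding is not
   implemented: a uniform threshold is what keeps networks comparable
   across groups.
5. **Stability** (`natural_connectivity`, `removal_simulation`,
   `stability_trend`). Natural connectivity is
   `ln(mean(exp(lambda_i)))` over the eigenvalues of the unsigned,
   unweighted adjacency matrix — the log of the average closed-walk
   weight, a spectral robustness index that degrades smoothly as routes
   are lost. Extinction is simulated by removing `round(p * N)` uniformly
   chosen nodes (100 replicates per fraction by default); surviving
   isolated nodes stay in the node set, a conservative choice that keeps
   the index comparable across replicates. Robustness-versus-salinity
   trends are fit at fixed removal fractions.
6. **Turnover** (`network_community`, `community_overlap`,
   `community_similarity`, `turnover_trend`). A *network community* is
   the node set of one group's network. Overlaps between communities are
   decomposed by abundance class. Compositional similarity is
   1 − Bray-Curtis between the communities' mean-relative-abundance
   vectors over the union of their members; the mean abundances are
   computed within each network's own sample group (a presence/absence
   mode is available; abundance weighting is the default because the
   class decomposition is abundance-driven). Adjacent pairs
   (n1→n2→…) are the default bookkeeping; the similarity-versus-
   salinity-span regression uses all pairs.
7. **Biosphere roles** (`relative_degree`, `class_gap`, `freeman_theta`,
   `role_trends`, `levins_breadth`, `breadth_comparison`). Relative
   degree divides each node's degree by its network's average degree, so
   importance is comparable across networks of different size; its mean
   over a network's nodes is exactly 1 by construction, which the tests
   assert at 1e-12. The abundant-vs-rare contrast per network is the
   difference in mean relative degree and Freeman's theta,
   `|P - Q| / (n_a * n_b)` over all cross-pairs (ties count for
   neither) — an ordinal effect size in [0, 1] invariant under monotone
   transforms. Node-level relative-degree trends pool nodes across
   networks, each carrying its network's mean salinity (per-network-mean
   regressions are easily assembled from the records if preferred);
   theta is computed per network on relative degrees and regressed on
   group salinity — one point per network. Levins niche breadth is
   `B = 1 / sum(p_j^2)` over a taxon's occupancy proportions, between 1
   (single sample) and the number of samples (even occupancy); abundant
   and rare breadths are compared with a two-sided Wilcoxon rank-sum
   test.

## The synthetic community generator

Sequencing data for gradient surveys cannot be shipped inside a package,
so every stage is exercised against `simulate_gradient()`, a generative
model with the statistical structure the analysis assumes:

* **Design.** Three transects of sixteen consecutive sites with salinity
  evenly spaced over 0.8–21 g/L plus small jitter, eight samples per
  salinity group — the sampling design of the target system.
* **Hyperdominance by construction.** Base abundances follow the
  lognormal quantile spectrum whose width is solved in closed form from
  the hyperdominance target: for the top fraction `q` of taxa to carry a
  share `s` of reads, `sigma = qnorm(1-q) - qnorm(1-s)`. Each taxon's
  base is then anchored by dividing out its expected niche-and-factor
  multiplier, so the realised mean relative abundances reproduce the
  designed spectrum instead of drifting with the niche draws. With the
  default 2700 taxa, `q = 0.065` and `s = 0.70`, the downstream
  classifier recovers ~6–7 % abundant taxa holding ~70–75 % of reads.
* **Gaussian niches.** Each taxon has a salinity optimum (Beta-skewed
  toward the freshwater end, shape 2.2) and a tolerance sigma drawn per
  abundance class (defaults 10 / 6 / 3.5 g/L for abundant /
  intermediate / rare), giving the empirical signatures of diversity
  decline and taxonomic turnover along the gradient and broader niches
  for abundant than rare taxa.
* **Module-structured associations.** Taxa are assigned to equal-sized
  modules (default 12) whose members share a latent standard-normal
  factor per sample, entering log-abundance with a loading that declines
  linearly with salinity (`association_strength_decay`, default
  0.013 per g/L from a freshwater loading of 1.05). Modules additionally
  fragment along the gradient through a *halving cascade*: the salinity
  range is cut into equal intervals and within each successive interval
  a module's factor is replaced by factors of twice as many nested
  blocks (1, 2, 4, … up to `n_submodules`, default 6). Equal module
  sizes and synchronous halving keep the edge mass balanced across
  components, which is what makes the modularity of the resulting
  networks rise cleanly as they fragment; staggered or blended
  fragmentation schemes produce transient imbalance (a few components
  hoarding edge mass) and noisy, non-monotone modularity.
* **Counts.** Per sample, a multinomial at the sequencing depth (default
  51,323 reads) over the softmax of log intensities, so column sums
  equal the depth exactly and rarefaction is exercised meaningfully.
  Taxon-by-sample lognormal noise (sd 0.10) represents unmodelled
  variation.
* **Determinism.** One `set.seed(design$seed)` with a fixed draw order
  makes the whole simulation a deterministic function of the design;
  pipeline stages derive their own seeds from one root via
  `derive_seed(seed, stage)`, a documented hash, so a single integer
  reproduces a full run while stages remain independently re-runnable.

A quantitative constraint worth knowing: with eight samples per group
and a correlation threshold of 0.96, a taxon can only carry edges if its
factor-loading-to-noise variance ratio exceeds roughly 24. Counting
noise on the log scale is about `1/count`, so taxa observed at a handful
of reads per sample cannot form edges no matter how strongly they load
on a factor. Rare taxa enter networks only as *locally abundant narrow
specialists* — near the 0.01 % mean-abundance boundary, concentrated in
one stretch of the gradient. The generator produces such taxa naturally
(narrow niches plus the anchoring), and this is also the only way rare
taxa can plausibly appear in the real networks.

Two presets package the planted-effect experiments used in validation:
`design_association_decay()` (1000 taxa, depth 50,000) plants monotone
decay of network complexity and robustness; `design_hub_erosion()`
(3500 taxa, depth 100,000, class-specific loadings: abundant 1.45
decaying fully, intermediate 1.05 decaying at a third of the rate, rare
0.95 nearly constant, niche optima uniform so rare specialists exist at
every salinity) plants the role reversal: abundant relative degree
falls, rare relative degree rises, and Freeman's theta declines. At
these sizes a full six-network replicate runs in well under a second,
so the validation suite measures recovery power over 20 seeds.

What the generator does **not** emulate: phylogenetic structure and
taxonomy, sequencing error and chimeras, overdispersion beyond the
lognormal noise, non-Gaussian (e.g. bimodal) niches, true ecological
interactions as opposed to covariance, and spatial autocorrelation
between transects. Passing tests therefore show the pipeline recovers
planted covariance and niche structure from compositional counts — not
that any particular real community behaves this way.

## Numerical choices and degenerate inputs

* Correlation screening uses `|r| >= threshold` exactly; taxa with
  constant CLR vectors (undefined correlations) are excluded with a
  warning.
* Natural connectivity factors out the largest eigenvalue before
  exponentiation, is computed by symmetric eigendecomposition, and is
  validated against a matrix-exponential (Pade) oracle to 1e-9; the
  edgeless graph gives exactly 0.
* Abundance-class thresholds are strict inequalities with a 1e-12
  absolute guard, so a taxon sitting numerically on 0.1 % or 0.01 % is
  intermediate.
* The power-law fit needs at least three distinct positive degrees;
  otherwise it reports `NA` with a warning rather than a misleading
  R-squared. Modularity of an edgeless graph is likewise `NA`.
* An empty prevalence-filter result, a network with no edges, or a
  network missing one abundance class are all reported (warning or `NA`
  with a flag) instead of failing the whole run; `role_trends` drops
  networks where a class is absent from the gap and theta regressions.
* Group counts not divisible by the group number fail loudly by
  default; `remainder = "trim"` drops the highest-salinity remainder.

## Problem sizes

The shipped analysis scripts and the validation suite run the full
design (2700 taxa, 48 samples, depth 51,323) for the main workflow, and
the reduced planted-effect designs above for power measurements; these
sizes were chosen so a complete replicate is seconds and a 20-seed
power study is minutes on a laptop. The random-forest defaults (1000
iterations, 500 trees) reproduce the heavy protocol; the analysis
scripts use 50 iterations of 300 trees, which leaves the ranking of
clearly informative taxa unchanged in our planted tests.

## Known limitations

Pearson-on-CLR with a uniform threshold is a deliberately simple
association measure: it cannot separate direct from indirect
association, and at n = 8 the estimation noise of r is substantial
(sd about 0.07 near the threshold), so individual edges are unreliable
even though network-level summaries are stable. The modularity
algorithm (greedy CNM) is one of several reasonable choices and can
split differently from other optimisers on near-degenerate partitions.
Freeman's theta is an absolute effect size: if the rare biosphere
*overtakes* the abundant one, theta rises again, so a monotone theta
decline is evidence of converging roles, not of reversal beyond parity.
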