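# salinet

Co-occurrence network analysis of microbial communities along salinity
gradients.

## The problem

In estuaries, rivers grade into the sea and salinity rises from under
1 g/L to above 20 g/L within a few kilometres. Along such gradients
microbial diversity declines, community composition turns over, and —
the question this package addresses quantitatively — the *association
networks* among taxa simplify and destabilise. A second question rides
on the first: microbial communities are hyperdominant (a few percent of
taxa hold most of the reads), so who actually maintains the network —
the abundant biosphere (taxa above 0.1 % mean relative abundance) or
the rare one (below 0.01 %) — and how does that division of labour
shift under stress?

salinet implements the full analysis chain for these questions, for
anyone with a taxon-by-sample count table and per-sample salinity:
rarefaction and biosphere classification; Mantel tests and diversity
trends; random-forest salinity-biomarker selection with cross-validated
biomarker counts; per-group co-occurrence networks from CLR-transformed
counts with a uniform correlation threshold; topology, modularity and
power-law degree fits; robustness under random node removal; turnover of
network membership; and the biosphere-role statistics. A synthetic
gradient-community generator with Gaussian niches, a hyperdominant
abundance spectrum and module-structured associations makes every stage
testable without sequencing data.

## The statistics at the core

For each of six salinity-ordered groups of samples, a network is built
from Pearson correlations of CLR-transformed counts
(edge iff |r| ≥ 0.96 across the group's samples). On each network:

* **Natural connectivity** — with adjacency eigenvalues λ₁…λ_N,
  `nc = ln((1/N) Σ exp(λᵢ))`: a spectral robustness index tracked while
  random fractions of nodes are removed.
* **Krackhardt connectedness** — the fraction of node pairs joined by a
  path: 0 for a graph without links, 1 for a connected graph.
* **Relative degree** — node degree divided by the network's average
  degree, making node importance comparable across networks (its mean
  over a network is exactly 1).
* **Freeman's θ** — with P and Q the counts of cross-pairs where an
  abundant node's relative degree exceeds (falls below) a rare node's,
  `θ = |P − Q| / (n_a · n_r)` ∈ [0, 1]: the ordinal effect size of the
  abundant-vs-rare contrast, one value per network.
* **Levins niche breadth** — `B = 1 / Σ p_j²` over a taxon's occupancy
  proportions, from 1 (one sample) to the number of samples (even
  occupancy), compared between biospheres by Wilcoxon rank-sum test.

Trends of all of these against group mean salinity are ordinary
least-squares fits with two-sided slope tests.

## Worked example

```r
library(salinet)

# a reduced survey: 48 samples over 0.8-21 g/L, 1000 taxa
design <- design_association_decay(seed = 1)
sim <- simulate_gradient(design)

groups <- assign_salinity_groups(sim$metadata, n_groups = 6)

# networks for the freshest and the saltiest group
nets <- lapply(c(1, 6), function(i) {
  ids <- subset(groups$assignment, group == groups$groups$group[i])$sample_id
  kept <- prevalence_filter(sim$counts, ids, min_prevalence = 1)
  build_network(clr_transform(kept), threshold = 0.96,
                group_salinity = groups$groups$mean_salinity[i],
                group_id = groups$groups$group[i])
})
print(nets[[1]])
#> cooc_network n1: 527 nodes, 4102 edges (|r| >= 0.96, salinity 1.95)
print(nets[[2]])
#> cooc_network n6: 261 nodes, 305 edges (|r| >= 0.96, salinity 19.88)

topo <- do.call(rbind, lapply(nets, topology))
round(topo[, c("avg_degree", "density", "connectedness", "modularity")], 3)
#>   avg_degree density connectedness modularity
#> 1     15.567   0.030         0.081      0.893
#> 2      2.337   0.009         0.016      0.972

removal_simulation(nets[[1]], fractions = c(0.1, 0.5),
                   n_replicates = 50, seed = 7)
#> robustness_result: 2 fractions x 50 replicates
#>  fraction avg_degree_mean avg_degree_sd natural_connectivity_mean
#>       0.1       13.983291     0.2757723                  22.14777
#>       0.5        7.644563     0.5104807                  11.00347
#>  natural_connectivity_sd
#>                0.8563556
#>                1.3526315
```

Read: the freshwater-end network is an order of magnitude denser and
better connected than the seawater-end one, and after removing half its
nodes it still retains a natural connectivity (11.0) far above anything
the seawater network starts with — complexity and robustness both
collapse along the gradient.

## The analysis workflow

`analysis/` contains the numbered drivers for a complete study on the
default simulated community (2700 taxa, 48 samples, depth 51,323):

```sh
Rscript analysis/01_simulate.R        # community + metadata -> results/data/
Rscript analysis/02_prep.R            # rarefy, classify, group
Rscript analysis/03_gradient_stats.R  # Mantel, alpha-diversity trends
Rscript analysis/04_biomarkers.R      # random-forest biomarkers
Rscript analysis/05_networks.R        # six networks + topology trends
Rscript analysis/06_stability.R       # node-removal robustness
Rscript analysis/07_turnover.R        # network-community turnover
Rscript analysis/08_roles.R           # relative degree, theta, niche breadth
```

Each script states what it found and writes its tables under
`results/`. On the default run, network size falls from 660 to 266
nodes and average degree from 12.4 to 2.3 between the freshest and
saltiest group; all topology and robustness trends are significant in
the expected direction; the overlap between adjacent network
communities is dominated by abundant taxa (38–61 %) with almost no rare
taxa (0–2.5 %); and the abundant biosphere's relative degree declines
with salinity while the rare biosphere's rises, with Freeman's θ
falling from ≈0.67 to ≈0.41. `run_pipeline()` performs the same chain
in one call from a validated `pipeline_config()`.

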