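# Independent oracles and small fixture builders used across the suite.

# Natural connectivity via the matrix exponential (Pade approximation in
# Matrix::expm), independent of the eigendecomposition route in the package.
oracle_natural_connectivity <- function(a) {
  e <- as.matrix(Matrix::expm(Matrix::Matrix(a * 1, sparse = FALSE)))
  log(sum(diag(e)) / nrow(a))
}

# Freeman's theta by explicit double loop.
oracle_theta <- function(a, b) {
  p <- 0L; q <- 0L
  for (x in a) for (y in b) {
    if (x > y) p <- p + 1L
    if (x < y) q <- q + 1L
  }
  abs(p - q) / (length(a) * length(b))
}

# Krackhardt connectedness by brute-force transitive closure.
oracle_connectedness <- function(a) {
  n <- nrow(a)
  reach <- (a > 0) | diag(n) > 0
  for (k in seq_len(n))
    reach <- reach | (reach %*% reach) > 0
  (sum(reach) - n) / (n * (n - 1))
}

# Symmetric 0/1 adjacency of an Erdos-Renyi draw.
random_adjacency <- function(n, p) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

# Small labelled count matrix.
toy_counts <- function(x, taxa = NULL, samples = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  rownames(x) <- taxa %||% sprintf("t%d", seq_len(nrow(x)))
  colnames(x) <- samples %||% sprintf("s%d", seq_len(ncol(x)))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A CLR-like matrix with two planted perfectly-correlated blocks plus noise
# rows; rows are taxa, columns samples.
planted_block_clr <- function(n_noise = 4, n_samples = 8, seed = 42) {
  set.seed(seed)
  f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
  m <- rbind(f1, 2 * f1 + 1, f2, -f2,
             matrix(rnorm(n_noise * n_samples), n_noise))
  rownames(m) <- sprintf("t%d", seq_len(nrow(m)))
  m
}

# Tiny network community constructor for turnover tests.
toy_community <- function(nodes, classes, abundance,
                          id = "c", salinity = 1) {
  structure(list(id = id, salinity = salinity, nodes = nodes,
                 classes = factor(classes,
                                  levels = c("abundant", "intermediate",
                                             "rare")),
                 abundance = stats::setNames(abundance, nodes)),
            class = "network_community")
}

# One small co-occurrence network from a simulated design; used for the
# relative-degree identity checks.
small_sim_network <- function(seed, n_taxa = 80, n_modules = 4) {
  d <- gradient_design(n_transects = 1, sites_per_transect = 12,
                       n_taxa = n_taxa, n_modules = n_modules,
                       n_submodules = 1, sequencing_depth = 5000,
                       hyperdominance = c(fraction_abundant = 0.2,
                                          target_abundance_share = 0.6),
                       association_strength_decay = 0, seed = seed)
  sim <- simulate_gradient(d)
  tab <- prevalence_filter(sim$counts, min_prevalence = 0.5)
  build_network(clr_transform(tab), threshold = 0.7, group_salinity = 1)
}
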