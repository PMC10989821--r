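#' Describe a synthetic salinity-gradient community design
#'
#' Collects every knob of the gradient community generator into one validated
#' object. The defaults emulate the sampling design the package targets:
#' three river-to-sea transects of sixteen consecutive sites spanning roughly
#' 0.8--21 g/L salinity, a hyperdominant abundance spectrum in which a small
#' fraction of taxa holds most reads, Gaussian niche responses that thin the
#' community out as salinity rises, and module-structured positive
#' associations whose strength decays linearly with salinity.
#'
#' The lognormal width of the base abundance spectrum is not a free knob: it
#' is solved from `hyperdominance` so that the taxa above the abundant
#' threshold are (in expectation) exactly the top `fraction_abundant` of taxa
#' and carry `target_abundance_share` of the reads. For a lognormal spectrum
#' the share of total mass held by the top fraction `q` is
#' `1 - pnorm(qnorm(1 - q) - sigma)`, giving
#' `sigma = qnorm(1 - q) - qnorm(1 - share)` in closed form.
#'
#' @param n_transects Number of transects.
#' @param sites_per_transect Consecutive sites per transect.
#' @param salinity_range Length-2 numeric, min and max salinity in g/L.
#' @param n_taxa Number of taxa in the pool.
#' @param hyperdominance Named numeric with `fraction_abundant` (fraction of
#'   taxa forming the abundant biosphere) and `target_abundance_share`
#'   (fraction of reads they should carry).
#' @param niche_width_by_class Named numeric, Gaussian niche tolerance sigma
#'   (salinity units) per abundance class. Abundant taxa default to broader
#'   niches than rare taxa.
#' @param n_modules Number of association modules.
#' @param n_submodules Final number of nested sub-blocks a module
#'   fragments into at the seawater end of the gradient (1 disables
#'   fragmentation). Fragmentation proceeds as a halving cascade: the
#'   salinity range is split into equal intervals, and within each
#'   successive interval every module's shared factor is replaced by
#'   factors of twice as many nested blocks (1, 2, 4, ... up to
#'   `n_submodules`), so networks coarsen from whole coherent modules
#'   into small sub-blocks as stress rises while block sizes stay
#'   balanced.
#' @param base_loading Latent-factor loading at the freshwater end.
#' @param association_strength_decay Decline of the loading per g/L salinity.
#' @param class_loading Multiplier on `base_loading` per abundance class.
#' @param class_decay Multiplier on the decay slope per abundance class.
#' @param amp_jitter Length-2 range of per-taxon loading amplitude jitter.
#' @param noise_sd Taxon-by-sample idiosyncratic noise SD on the log scale.
#' @param niche_skew Second shape parameter of the Beta law placing niche
#'   optima; values > 1 skew optima toward the freshwater end, which is what
#'   drives the expected richness decline with salinity.
#' @param sequencing_depth Reads per sample (multinomial total).
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the design including this seed.
#' @return A `gradient_design` list.
#' @seealso [simulate_gradient()]
#' @export
gradient_design <- function(n_transects = 3,
                            sites_per_transect = 16,
                            salinity_range = c(0.8, 21),
                            n_taxa = 2700,
                            hyperdominance = c(fraction_abundant = 0.065,
                                               target_abundance_share = 0.70),
                            niche_width_by_class = c(abundant = 10,
                                                     intermediate = 6,
                                                     rare = 3.5),
                            n_modules = 12,
                            n_submodules = 6,
                            base_loading = 1.05,
                            association_strength_decay = 0.013,
                            class_loading = c(abundant = 1, intermediate = 1,
                                              rare = 1),
                            class_decay = c(abundant = 1, intermediate = 1,
                                            rare = 1),
                            amp_jitter = c(0.85, 1.15),
                            noise_sd = 0.10,
                            niche_skew = 2.2,
                            sequencing_depth = 51323,
                            seed = 1) {
  d <- list(n_transects = n_transects, sites_per_transect = sites_per_transect,
            salinity_range = as.numeric(salinity_range), n_taxa = n_taxa,
            hyperdominance = hyperdominance,
            niche_width_by_class = niche_width_by_class,
            n_modules = n_modules, n_submodules = n_submodules,
            base_loading = base_loading,
            association_strength_decay = association_strength_decay,
            class_loading = class_loading, class_decay = class_decay,
            amp_jitter = as.numeric(amp_jitter), noise_sd = noise_sd,
            niche_skew = niche_skew, sequencing_depth = sequencing_depth,
            seed = seed)
  validate_design(d)
  class(d) <- "gradient_design"
  d
}

validate_design <- function(d) {
  with(d, {
    if (length(salinity_range) != 2 || salinity_range[1] >= salinity_range[2])
      stop("salinity_range must satisfy min < max")
    counts <- c(n_transects, sites_per_transect, n_taxa, n_modules)
    if (any(counts < 1) || any(counts != round(counts)))
      stop("n_transects, sites_per_transect, n_taxa and n_modules must be counts >= 1")
    if (n_taxa < n_modules)
      stop(sprintf("degenerate design: n_taxa (%d) < n_modules (%d)",
                   n_taxa, n_modules))
    fa <- hyperdominance[["fraction_abundant"]]
    sh <- hyperdominance[["target_abundance_share"]]
    if (fa <= 0 || fa >= 1) stop("fraction_abundant must lie in (0, 1)")
    if (sh <= fa || sh >= 1)
      stop("target_abundance_share must lie in (fraction_abundant, 1)")
    if (sequencing_depth <= 0) stop("sequencing_depth must be positive")
    if (!all(abundance_class_levels %in% names(niche_width_by_class)))
      stop("niche_width_by_class must name abundant, intermediate and rare")
    if (any(niche_width_by_class <= 0)) stop("niche widths must be positive")
    if (noise_sd < 0) stop("noise_sd must be non-negative")
    if (n_submodules < 1 || n_submodules != round(n_submodules))
      stop("n_submodules must be a count >= 1")
  })
  invisible(d)
}

#' Simulate a gradient microbial community
#'
#' Draws a taxa-by-samples count table, sample metadata and a ground-truth
#' record from a [gradient_design()]. Expected composition of taxon i in
#' sample j is proportional to
#' `base_i * exp(-(s_j - mu_i)^2 / (2 sigma_i^2)) * exp(l_ij * F[m(i), j])`,
#' where `mu_i`/`sigma_i` are the taxon's Gaussian niche optimum and
#' tolerance, `F` is an iid standard-normal latent factor per module and
#' sample, and the loading `l_ij` declines linearly with salinity at
#' `association_strength_decay` (floored at zero). Counts are drawn per
#' sample from a multinomial at `sequencing_depth`, so column sums equal the
#' depth exactly.
#'
#' The base abundances are anchored to the lognormal quantile spectrum
#' calibrated from the hyperdominance target: each taxon's base is the
#' target spectrum value divided by its expected niche-and-factor
#' multiplier (averaged over samples, with the lognormal factor mean
#' `exp(l^2/2)`), so the expected mean relative abundances reproduce the
#' designed hyperdominant spectrum rather than drifting with the niche
#' draws. Taxon-to-sample noise is added on the log scale before the
#' softmax normalisation. Ground-truth abundance classes are assigned from
#' the target spectrum with the same thresholds the downstream classifier
#' uses (abundant > 0.1 %, rare < 0.01 % mean relative abundance).
#'
#' @param design A [gradient_design()].
#' @return A list of class `gradient_sim` with elements `counts` (integer
#'   matrix, taxa x samples), `metadata` (data frame: sample_id, transect,
#'   site, latitude, longitude, salinity) and `ground_truth` (per-taxon
#'   data frame with mu, sigma, class, module, base abundance, plus the
#'   design).
#' @export
simulate_gradient <- function(design) {
  stopifnot(inherits(design, "gradient_design"))
  validate_design(design)
  set.seed(design$seed)
  smin <- design$salinity_range[1]
  smax <- design$salinity_range[2]
  n_s <- design$n_transects * design$sites_per_transect
  n_t <- design$n_taxa

  # --- samples: evenly spaced salinity per transect plus small jitter ---
  transect <- rep(seq_len(design$n_transects), each = design$sites_per_transect)
  site <- rep(seq_len(design$sites_per_transect), design$n_transects)
  sal0 <- rep(seq(smin, smax, length.out = design$sites_per_transect),
              design$n_transects)
  salinity <- pmax(0.05, sal0 + stats::rnorm(n_s, 0, 0.15))
  latitude <- 36.0 + (site - 1) * 0.014   # ~1.5 km spacing along the transect
  longitude <- 120.3 + (transect - 1) * 0.5
  sample_id <- sprintf("T%d_S%02d", transect, site)
  meta <- data.frame(sample_id = sample_id, transect = transect, site = site,
                     latitude = latitude, longitude = longitude,
                     salinity = salinity, stringsAsFactors = FALSE)

  # --- taxa: lognormal quantile spectrum calibrated to the hyperdominance ---
  fa <- design$hyperdominance[["fraction_abundant"]]
  sh <- design$hyperdominance[["target_abundance_share"]]
  sigma_ln <- stats::qnorm(1 - fa) - stats::qnorm(1 - sh)
  target <- rev(exp(sigma_ln * stats::qnorm(stats::ppoints(n_t))))
  rel_target <- target / sum(target)    # taxon 1 = most abundant
  cls <- ifelse(rel_target > 1e-3, "abundant",
                ifelse(rel_target < 1e-4, "rare", "intermediate"))
  cls <- factor(cls, levels = abundance_class_levels)

  mu <- (smin - 2) + (smax - smin + 4) *
    stats::rbeta(n_t, 1, design$niche_skew)
  sigma <- design$niche_width_by_class[as.character(cls)] *
    stats::runif(n_t, 0.8, 1.2)
  # equal-size modules (random membership) keep per-module edge mass even;
  # final sub-blocks are nested round-robin within each module
  n_sub <- design$n_submodules
  module <- sample(rep_len(seq_len(design$n_modules), n_t))
  sub_idx <- integer(n_t)
  for (m in seq_len(design$n_modules)) {
    idx <- which(module == m)
    sub_idx[idx] <- rep_len(seq_len(n_sub), length(idx))
  }
  submodule <- (module - 1) * n_sub + sub_idx
  amp <- stats::runif(n_t, design$amp_jitter[1], design$amp_jitter[2])

  # --- latent factors: halving cascade. The salinity range is cut into
  # equal intervals (levels); within level l every module's factor is a
  # set of min(2^(l-1), n_sub) nested block factors, so modules are
  # coherent wholes at the freshwater end and balanced small blocks at
  # the seawater end ---
  n_levels <- if (n_sub == 1) 1L else as.integer(ceiling(log2(n_sub))) + 1L
  blocks_per_level <- pmin(2^(seq_len(n_levels) - 1), n_sub)
  lev <- pmax(1, pmin(n_levels,
                      1 + floor((salinity - smin) /
                                  ((smax - smin) / n_levels))))
  fac <- matrix(0, n_t, n_s)
  for (l in seq_len(n_levels)) {
    bl <- blocks_per_level[l]
    g <- matrix(stats::rnorm(design$n_modules * bl * n_s),
                design$n_modules * bl, n_s)
    cols <- which(lev == l)
    if (length(cols)) {
      block <- ceiling(sub_idx * bl / n_sub)
      rowid <- (module - 1) * bl + block
      fac[, cols] <- g[rowid, cols, drop = FALSE]
    }
  }

  l0 <- design$base_loading * design$class_loading[as.character(cls)] * amp
  slope <- design$association_strength_decay *
    design$class_decay[as.character(cls)]
  loading <- pmax(0, outer(l0, rep(1, n_s)) -
                       outer(slope, salinity - smin))

  niche <- -outer(mu, salinity, function(m, s) (s - m)^2) / (2 * sigma^2)
  # anchor each taxon's base so its expected mean intensity hits the target
  mult <- rowMeans(exp(niche + loading^2 / 2))
  base <- target / mult
  eta <- log(base) + niche + loading * fac +
    matrix(stats::rnorm(n_t * n_s, 0, design$noise_sd), n_t, n_s)

  counts <- matrix(0L, n_t, n_s,
                   dimnames = list(sprintf("ASV_%04d", seq_len(n_t)),
                                   sample_id))
  for (j in seq_len(n_s)) {
    e <- eta[, j]
    p <- exp(e - max(e))
    counts[, j] <- stats::rmultinom(1, design$sequencing_depth, p / sum(p))[, 1]
  }

  gt <- list(taxa = data.frame(taxon = rownames(counts), base = rel_target,
                               class = as.character(cls), mu = mu,
                               sigma = as.numeric(sigma),
                               module = module, submodule = submodule,
                               amplitude = amp,
                               stringsAsFactors = FALSE),
             sigma_lognormal = sigma_ln,
             design = unclass(design))
  structure(list(counts = counts, metadata = meta, ground_truth = gt),
            class = "gradient_sim")
}

#' @export
print.gradient_sim <- function(x, ...) {
  cat(sprintf("gradient_sim: %d taxa x %d samples, depth %d, salinity %.2f-%.2f g/L\n",
              nrow(x$counts), ncol(x$counts),
              x$ground_truth$design$sequencing_depth,
              min(x$metadata$salinity), max(x$metadata$salinity)))
  invisible(x)
}

#' Write a simulated community to plain-text files
#'
#' Writes the count table and metadata as TSV and the ground truth as a JSON
#' sidecar, the on-disk convention used throughout the package.
#'
#' @param sim A `gradient_sim`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "gradient_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "abundance.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  write_abundance_tsv(sim$counts, paths[["counts"]])
  write_metadata_tsv(sim$metadata, paths[["metadata"]])
  jsonlite::write_json(sim$ground_truth, paths[["ground_truth"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Preset design: association decay along the gradient
#'
#' A reduced-size design used for the planted-effect experiments on network
#' complexity and stability: module associations are strong at the
#' freshwater end and decay with salinity for every abundance class, so
#' per-group networks built at a fixed correlation threshold lose nodes,
#' links and robustness as salinity rises while fragmenting into more
#' modules.
#'
#' @param seed Integer seed.
#' @param n_taxa,sequencing_depth Problem size; defaults keep a full
#'   six-network replicate in the order of seconds.
#' @return A `gradient_design`.
#' @export
design_association_decay <- function(seed = 1, n_taxa = 1000,
                                     sequencing_depth = 50000) {
  gradient_design(n_taxa = n_taxa, sequencing_depth = sequencing_depth,
                  hyperdominance = c(fraction_abundant = 0.1,
                                     target_abundance_share = 0.6),
                  seed = seed)
}

#' Preset design: erosion of abundant-taxon hubs
#'
#' A design in which abundant taxa start as strongly loaded hubs whose
#' associations decay quickly with salinity, while rare taxa keep modest but
#' persistent associations. Networks built along the gradient then show the
#' planted role reversal: the relative degree of abundant taxa falls with
#' salinity, that of rare taxa rises, and the abundant-vs-rare effect size
#' (Freeman's theta) declines.
#'
#' @inheritParams design_association_decay
#' @return A `gradient_design`.
#' @export
design_hub_erosion <- function(seed = 1, n_taxa = 3500,
                               sequencing_depth = 100000) {
  gradient_design(n_taxa = n_taxa, sequencing_depth = sequencing_depth,
                  base_loading = 1.0,
                  class_loading = c(abundant = 1.45, intermediate = 1.05,
                                    rare = 0.95),
                  niche_width_by_class = c(abundant = 10, intermediate = 6,
                                           rare = 1.7),
                  class_decay = c(abundant = 1, intermediate = 0.33,
                                  rare = -0.07),
                  association_strength_decay = 0.04,
                  amp_jitter = c(0.95, 1.05),
                  niche_skew = 1,
                  seed = seed)
}

#' Simulate a planted biomarker design
#'
#' A small regression testbed for the biomarker-discovery stage: a handful
#' of informative taxa jointly determine salinity through independent latent
#' components (so no strict subset of them predicts it fully), while the
#' remaining taxa are pure noise.
#'
#' @param n_samples,n_taxa,n_informative Problem size.
#' @param noise_sd Observation noise SD on the informative features.
#' @param seed Integer seed.
#' @return List with `features` (samples x taxa matrix), `salinity`, and
#'   `informative` (names of the planted taxa).
#' @export
simulate_planted_biomarkers <- function(n_samples = 48, n_taxa = 50,
                                        n_informative = 3, noise_sd = 0.1,
                                        seed = 1) {
  stopifnot(n_informative >= 1, n_taxa >= n_informative, n_samples >= 10)
  set.seed(seed)
  u <- matrix(stats::rnorm(n_samples * n_informative), n_samples)
  salinity <- as.numeric(scale(rowSums(u))) * 5 + 10
  feats <- matrix(stats::rnorm(n_samples * n_taxa), n_samples, n_taxa)
  feats[, seq_len(n_informative)] <- u +
    matrix(stats::rnorm(n_samples * n_informative, 0, noise_sd), n_samples)
  colnames(feats) <- sprintf("taxon_%02d", seq_len(n_taxa))
  rownames(feats) <- sprintf("S%02d", seq_len(n_samples))
  list(features = feats, salinity = salinity,
       informative = colnames(feats)[seq_len(n_informative)])
}
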