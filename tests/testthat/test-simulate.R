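test_that("simulation is a deterministic function of the design", {
  d <- gradient_design(n_taxa = 120, sequencing_depth = 2000, seed = 11)
  a <- simulate_gradient(d)
  b <- simulate_gradient(d)
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$ground_truth$taxa, b$ground_truth$taxa)
})

test_that("column sums equal the sequencing depth exactly", {
  sim <- simulate_gradient(gradient_design(n_taxa = 150,
                                           sequencing_depth = 3141,
                                           seed = 2))
  expect_true(all(colSums(sim$counts) == 3141))
  expect_equal(dim(sim$counts), c(150, 48))
})

test_that("degenerate designs are rejected with explanatory errors", {
  expect_error(gradient_design(n_taxa = 4, n_modules = 6), "degenerate")
  expect_error(gradient_design(salinity_range = c(5, 2)), "min < max")
  expect_error(gradient_design(hyperdominance =
                                 c(fraction_abundant = 0,
                                   target_abundance_share = 0.7)),
               "fraction_abundant")
  expect_error(gradient_design(sequencing_depth = 0), "positive")
})

test_that("hyperdominance target is realised downstream", {
  # fraction_abundant = 0.065 with a 70 % read share: the taxa the
  # downstream classifier calls abundant should be ~6-7 % of taxa and hold
  # ~70 % of reads.
  sim <- simulate_gradient(gradient_design(seed = 5))
  cls <- classify_abundance(sim$counts)
  frac <- mean(cls == "abundant")
  share <- sum(sim$counts[cls == "abundant", ]) / sum(sim$counts)
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.10)
  expect_gt(share, 0.65)
  expect_lt(share, 0.75)
})

test_that("richness declines along the gradient and abundant niches are broader", {
  sim <- simulate_gradient(gradient_design(seed = 7))
  tr <- linear_trend(sim$metadata$salinity,
                     alpha_diversity(sim$counts, "richness"))
  expect_lt(tr$slope, 0)
  expect_lt(tr$p_value, 0.05)
  gt <- sim$ground_truth$taxa
  expect_gt(mean(gt$sigma[gt$class == "abundant"]),
            mean(gt$sigma[gt$class == "rare"]))
})

test_that("without association decay the correlation structure is salinity-invariant", {
  # Control design: decay 0, a single association level, and flat niches, so
  # nothing ties the dependence structure to salinity.
  diffs <- sapply(1:3, function(s) {
    d <- gradient_design(n_taxa = 250, sequencing_depth = 20000,
                         association_strength_decay = 0, n_submodules = 1,
                         niche_width_by_class = c(abundant = 50,
                                                  intermediate = 50,
                                                  rare = 50),
                         niche_skew = 1, seed = s)
    sim <- simulate_gradient(d)
    grp <- assign_salinity_groups(sim$metadata, 6)
    mean_abs_r <- function(i) {
      ids <- grp$assignment$sample_id[grp$assignment$group ==
                                        grp$groups$group[i]]
      sub <- prevalence_filter(sim$counts, ids, 1)
      r <- stats::cor(t(clr_transform(sub)))
      mean(abs(r[upper.tri(r)]))
    }
    mean_abs_r(1) - mean_abs_r(6)
  })
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("simulations round-trip through the TSV/JSON writers", {
  sim <- simulate_gradient(gradient_design(n_taxa = 50,
                                           sequencing_depth = 1000,
                                           seed = 3))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_identical(read_abundance_tsv(paths[["counts"]]), sim$counts)
  meta <- read_metadata_tsv(paths[["metadata"]])
  expect_equal(meta$salinity, sim$metadata$salinity)
  gt <- jsonlite::read_json(paths[["ground_truth"]], simplifyVector = TRUE)
  expect_equal(gt$taxa$mu, sim$ground_truth$taxa$mu)
})
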