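test_that("a planted signal taxon is ranked first", {
  sim <- simulate_planted_biomarkers(n_taxa = 30, n_informative = 1,
                                     noise_sd = 0.05, seed = 1)
  rk <- rank_biomarkers(sim$features, sim$salinity, n_iterations = 5,
                        ntree = 150, seed = 1)
  expect_equal(rk$taxon[1], sim$informative)
  expect_true(all(diff(rk$mean_importance) <= 0))
})

test_that("ranking tolerates feature order permutation", {
  sim <- simulate_planted_biomarkers(n_taxa = 30, n_informative = 1,
                                     noise_sd = 0.05, seed = 2)
  perm <- sample(ncol(sim$features))
  rk <- rank_biomarkers(sim$features[, perm], sim$salinity,
                        n_iterations = 5, ntree = 150, seed = 2)
  expect_equal(rk$taxon[1], sim$informative)
})

test_that("a duplicated signal taxon joins the top ranks", {
  sim <- simulate_planted_biomarkers(n_taxa = 30, n_informative = 1,
                                     noise_sd = 0.05, seed = 3)
  feats <- cbind(sim$features,
                 dup = sim$features[, sim$informative] +
                   rnorm(nrow(sim$features), 0, 0.05))
  rk <- rank_biomarkers(feats, sim$salinity, n_iterations = 5,
                        ntree = 200, seed = 3)
  expect_true(all(c(sim$informative, "dup") %in% rk$taxon[1:5]))
})

test_that("the CV curve drops at the single informative taxon then stays flat", {
  sim <- simulate_planted_biomarkers(n_taxa = 20, n_informative = 1,
                                     noise_sd = 0.05, seed = 4)
  rk <- rank_biomarkers(sim$features, sim$salinity, n_iterations = 3,
                        ntree = 150, seed = 4)
  sel <- select_biomarker_count(sim$features, sim$salinity, rk,
                                folds = 5, repeats = 2, ntree = 100,
                                ns = 1:5, seed = 4)
  curve <- sel$cv_error_curve$mean_error
  noise_var <- var(sim$salinity)
  # n = 1 already predicts well, and adding noise taxa never brings the
  # error anywhere near the no-signal baseline
  expect_true(all(curve < 0.5 * noise_var))
  expect_lte(sel$selected_n, 2)
})

test_that("rank_biomarkers enforces its preconditions", {
  sim <- simulate_planted_biomarkers(seed = 5)
  expect_error(rank_biomarkers(sim$features[, 1, drop = FALSE],
                               sim$salinity, 1), "2 taxa")
  expect_error(rank_biomarkers(sim$features[1:5, ], sim$salinity[1:5], 1),
               "10 samples")
  expect_error(rank_biomarkers(sim$features, rep(1, nrow(sim$features)), 1),
               "constant")
})

test_that("colonizer labels follow the sign and significance of the trend", {
  set.seed(6)
  n <- 24
  sal <- seq(1, 20, length.out = n)
  feats <- cbind(down = 10 - 0.4 * sal + rnorm(n, 0, 0.1),
                 up = 0.2 * sal + rnorm(n, 0, 0.1),
                 flat = rnorm(n))
  lab <- classify_colonizers(feats, sal, colnames(feats))
  expect_equal(unname(lab["down"]), "low_salinity")
  expect_equal(unname(lab["up"]), "high_salinity")
  expect_equal(unname(lab["flat"]), "complex")
})
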