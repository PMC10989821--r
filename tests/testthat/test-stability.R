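test_that("natural connectivity matches the eigen anchors and the expm oracle", {
  k3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(natural_connectivity(k3), log((exp(2) + 2 * exp(-1)) / 3),
               tolerance = 1e-12)
  expect_equal(natural_connectivity(k3), 0.99629, tolerance = 1e-4)

  p3 <- matrix(0, 3, 3); p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1
  # closed form from the eigenvalues (sqrt(2), 0, -sqrt(2)) is the authority
  expect_equal(natural_connectivity(p3),
               log((exp(sqrt(2)) + 1 + exp(-sqrt(2))) / 3),
               tolerance = 1e-12)
  expect_equal(natural_connectivity(p3), 0.5797, tolerance = 1e-4)

  expect_equal(natural_connectivity(matrix(0, 5, 5)), 0)

  set.seed(12)
  for (i in 1:30) {
    a <- random_adjacency(sample(3:20, 1), runif(1, 0.1, 0.7))
    expect_equal(natural_connectivity(a), oracle_natural_connectivity(a),
                 tolerance = 1e-9)
  }
})

test_that("natural connectivity is edge-monotone and respects disjoint unions", {
  set.seed(13)
  for (i in 1:10) {
    a <- random_adjacency(10, 0.3)
    zero <- which(a == 0 & upper.tri(a), arr.ind = TRUE)
    if (nrow(zero) == 0) next
    pick <- zero[sample(nrow(zero), 1), ]
    b <- a; b[pick[1], pick[2]] <- b[pick[2], pick[1]] <- 1
    expect_gte(natural_connectivity(b), natural_connectivity(a) - 1e-12)
  }

  a <- random_adjacency(6, 0.5)
  b <- random_adjacency(4, 0.5)
  u <- rbind(cbind(a, matrix(0, 6, 4)), cbind(matrix(0, 4, 6), b))
  # ln of the size-weighted mean of per-component exp-eigenvalue means
  direct <- log((6 * exp(natural_connectivity(a)) +
                   4 * exp(natural_connectivity(b))) / 10)
  expect_equal(natural_connectivity(u), direct, tolerance = 1e-12)
})

test_that("removal at p = 0 is the identity and cliques stay cliques", {
  set.seed(14)
  a <- random_adjacency(12, 0.4)
  res <- removal_simulation(a, fractions = 0, n_replicates = 10, seed = 1)
  expect_equal(res$summary$avg_degree_sd, 0)
  expect_equal(res$summary$avg_degree_mean, mean(rowSums(a)))
  expect_equal(res$summary$natural_connectivity_mean,
               natural_connectivity(a))

  kn <- matrix(1, 10, 10) - diag(10)
  res2 <- removal_simulation(kn, fractions = 0.3, n_replicates = 20,
                             seed = 2)
  expect_true(all(res2$values$avg_degree == 7 - 1 + 0))  # n_remaining - 1 = 6
})

test_that("star-graph removal matches exhaustive enumeration", {
  star <- matrix(0, 6, 6)
  star[1, 2:6] <- star[2:6, 1] <- 1
  # remove 2 of 6 nodes: enumerate all 15 removal sets exactly
  combos <- combn(6, 2)
  exact <- apply(combos, 2, function(rm) {
    keep <- setdiff(1:6, rm)
    mean(rowSums(star[keep, keep]))
  })
  # bimodal: hub removed -> 4 isolated leaves (avg 0, prob 1/3);
  # hub kept -> star on 4 (avg 1.5, prob 2/3)
  expect_setequal(unique(exact), c(0, 1.5))
  expect_equal(mean(exact == 0), 1 / 3)
  res <- removal_simulation(star, fractions = 2 / 6, n_replicates = 600,
                            seed = 3)
  sim_vals <- res$values$avg_degree
  expect_setequal(unique(sim_vals), unique(exact))
  expect_lt(abs(mean(sim_vals == 0) - 1 / 3),
            4 * sqrt((1 / 3) * (2 / 3) / 600))
})

test_that("removal preconditions are enforced", {
  a <- random_adjacency(6, 0.5)
  expect_error(removal_simulation(a, fractions = 1), "\\[0, 1\\)")
  expect_error(removal_simulation(a, fractions = 0.99), "every node")
  expect_error(removal_simulation(a, fractions = 0.2, n_replicates = 0),
               "n_replicates")
})

test_that("stability trends detect planted density decay and not a null", {
  set.seed(15)
  robs <- lapply(c(0.5, 0.35, 0.22, 0.12, 0.06), function(p) {
    g <- igraph::sample_gnp(40, p)
    removal_simulation(g, fractions = 0.5, n_replicates = 30, seed = 1)
  })
  sal <- c(1, 5, 10, 15, 20)
  tr_nc <- stability_trend(robs, sal, 0.5, "natural_connectivity")
  tr_ad <- stability_trend(robs, sal, 0.5, "avg_degree")
  expect_lt(tr_nc$slope, 0); expect_lt(tr_nc$p_value, 0.05)
  expect_lt(tr_ad$slope, 0); expect_lt(tr_ad$p_value, 0.05)

  same <- lapply(1:4, function(i) {
    removal_simulation(random_adjacency(30, 0.3), fractions = 0.5,
                       n_replicates = 30, seed = i)
  })
  # identical graph distribution at all salinities: no significant trend
  tr0 <- stability_trend(same, c(1, 7, 14, 21), 0.5, "avg_degree")
  expect_gt(tr0$p_value, 0.05)
  expect_error(stability_trend(same[1:2], c(1, 2), 0.5), "3 networks")
  expect_error(stability_trend(same, c(1, 7, 14, 21), 0.4), "missing")
})
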