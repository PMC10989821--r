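test_that("relative degree is degree over network average, mean exactly 1", {
  # star on 5 nodes: hub degree 4, leaves 1, average 8/5
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:4))
  rd <- relative_degree(star)
  expect_equal(rd$relative_degree[rd$taxon == "hub"], 4 / (8 / 5))
  expect_equal(mean(rd$relative_degree), 1, tolerance = 1e-12)

  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- letters[1:6]
  expect_true(all(relative_degree(ring)$relative_degree == 1))

  lonely <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(lonely)$name <- letters[1:3]
  expect_error(relative_degree(lonely), "edgeless")
})

test_that("mean relative degree is 1 for simulated co-occurrence networks", {
  for (s in 1:8) {
    net <- small_sim_network(s)
    rd <- relative_degree(net)
    expect_equal(mean(rd$relative_degree), 1, tolerance = 1e-12)
  }
})

test_that("class gap is the difference of class means and flags absences", {
  rec <- data.frame(relative_degree = c(2, 2, 0.5, 0.5),
                    abundance_class = factor(
                      c("abundant", "abundant", "rare", "rare"),
                      levels = c("abundant", "intermediate", "rare")))
  g <- class_gap(rec)
  expect_equal(g$difference, 1.5)
  expect_true(g$defined)

  same <- data.frame(relative_degree = c(1, 2, 1, 2),
                     abundance_class = factor(
                       c("abundant", "abundant", "rare", "rare"),
                       levels = c("abundant", "intermediate", "rare")))
  expect_equal(class_gap(same)$difference, 0)

  no_rare <- data.frame(relative_degree = c(1, 2),
                        abundance_class = factor(
                          c("abundant", "abundant"),
                          levels = c("abundant", "intermediate", "rare")))
  g2 <- class_gap(no_rare)
  expect_false(g2$defined)
  expect_true(is.na(g2$difference))
})

test_that("Freeman's theta matches brute-force pair counting", {
  expect_equal(freeman_theta(c(3, 4), c(1, 2)), 1)
  expect_equal(freeman_theta(c(1, 2), c(1, 2)), 0)
  expect_equal(freeman_theta(c(1, 2, 3), 2), 0)

  set.seed(16)
  for (i in 1:200) {
    a <- sample(1:8, sample(1:12, 1), replace = TRUE)
    b <- sample(1:8, sample(1:12, 1), replace = TRUE)
    expect_identical(freeman_theta(a, b), oracle_theta(a, b))
  }
})

test_that("theta is symmetric and invariant under monotone transforms", {
  set.seed(17)
  a <- rnorm(9); b <- rnorm(7)
  expect_equal(freeman_theta(a, b), freeman_theta(b, a))
  expect_equal(freeman_theta(exp(a), exp(b)), freeman_theta(a, b))
  expect_equal(freeman_theta(rank(c(a, b))[1:9], rank(c(a, b))[10:16]),
               freeman_theta(a, b))
  expect_error(freeman_theta(numeric(0), 1), "non-empty")
})

test_that("role trends are flat across identical networks", {
  g <- igraph::make_graph(c("a", "b", "b", "c", "c", "a", "d", "a"),
                          directed = FALSE)
  cls <- factor(c(a = "abundant", b = "abundant", c = "rare", d = "rare"),
                levels = c("abundant", "intermediate", "rare"))
  recs <- lapply(1:4, function(i) {
    r <- relative_degree(g, cls)
    r$network_id <- paste0("n", i)
    r
  })
  rt <- role_trends(recs, salinities = c(1, 7, 14, 21))
  expect_equal(rt$abundant_rd$slope, 0, tolerance = 1e-12)
  expect_equal(rt$rare_rd$slope, 0, tolerance = 1e-12)
  expect_equal(rt$class_gap$slope, 0, tolerance = 1e-12)
  expect_equal(rt$theta$slope, 0, tolerance = 1e-12)
  expect_error(role_trends(recs[1:2]), "3 networks")
})

test_that("Levins breadth matches closed forms and its bounds", {
  unif <- toy_counts(matrix(5L, 1, 8))
  expect_equal(levins_breadth(unif)$levins_B, 8)
  expect_equal(levins_breadth(unif)$standardized_BA, 1)

  point <- toy_counts(matrix(c(9L, rep(0L, 7)), 1))
  expect_equal(levins_breadth(point)$levins_B, 1)
  expect_equal(levins_breadth(point)$standardized_BA, 0)

  half <- toy_counts(matrix(c(5L, 5L, 0L, 0L), 1))
  expect_equal(levins_breadth(half)$levins_B, 2)

  set.seed(18)
  x <- toy_counts(matrix(rpois(200, 3), 20, 10))
  x <- x[rowSums(x) > 0, , drop = FALSE]
  nb <- levins_breadth(x)
  expect_true(all(nb$levins_B >= 1 - 1e-12))
  expect_true(all(nb$levins_B <= 10 + 1e-12))
  # invariant to rescaling one taxon's counts
  x2 <- x; x2[3, ] <- x2[3, ] * 7L
  expect_equal(levins_breadth(x2)$levins_B[3], nb$levins_B[3])

  withzero <- toy_counts(rbind(c(1L, 2L), c(0L, 0L)))
  expect_warning(nb0 <- levins_breadth(withzero), "all-zero")
  expect_equal(nrow(nb0), 1)
})

test_that("niche breadth comparison separates planted classes", {
  cls <- factor(rep(c("abundant", "rare"), each = 10),
                levels = c("abundant", "intermediate", "rare"))
  rec <- data.frame(levins_B = c(rep(8, 10), rep(1, 10)),
                    abundance_class = cls)
  res <- breadth_comparison(rec)
  expect_lt(res$p_value, 0.001)

  tiny <- data.frame(levins_B = c(5, 1),
                     abundance_class = factor(c("abundant", "rare"),
                                              levels = levels(cls)))
  expect_no_error(breadth_comparison(tiny))
  expect_error(breadth_comparison(rec[cls == "rare", ]), "represented")
})
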