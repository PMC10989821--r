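test_that("perfectly correlated taxa are linked at any threshold", {
  m <- planted_block_clr()
  net <- build_network(m, threshold = 0.999)
  edges <- net$edges
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  expect_true("t1 t2" %in% key)  # t2 = 2*t1 + 1, r = 1
  expect_true("t3 t4" %in% key)  # t4 = -t3, r = -1
  neg <- edges[edges$from %in% c("t3", "t4") & edges$to %in% c("t3", "t4"), ]
  expect_equal(neg$sign, -1L)
  expect_equal(neg$r, -1)
})

test_that("strong negative correlations below -threshold keep their sign", {
  set.seed(8)
  x <- rnorm(8)
  y <- -x + rnorm(8, 0, 0.05)
  m <- rbind(a = x, b = y, c = rnorm(8))
  r <- cor(x, y)
  expect_lt(r, -0.96)
  net <- build_network(m, threshold = 0.96)
  e <- net$edges[net$edges$from == "a" & net$edges$to == "b", ]
  expect_equal(nrow(e), 1)
  expect_equal(e$sign, -1L)
  expect_equal(e$r, r)
})

test_that("raising the threshold never adds edges and taxon order is immaterial", {
  set.seed(9)
  m <- matrix(rnorm(15 * 8), 15, dimnames = list(sprintf("t%02d", 1:15),
                                                 NULL))
  lo <- build_network(m, threshold = 0.5)
  hi <- build_network(m, threshold = 0.8)
  ekey <- function(n) paste(pmin(n$edges$from, n$edges$to),
                            pmax(n$edges$from, n$edges$to))
  expect_true(all(ekey(hi) %in% ekey(lo)))

  perm <- sample(nrow(m))
  net_p <- build_network(m[perm, ], threshold = 0.5)
  expect_setequal(ekey(net_p), ekey(lo))
})

test_that("constant CLR vectors are excluded with a warning", {
  m <- planted_block_clr()
  m <- rbind(m, flat = rep(2, ncol(m)))
  expect_warning(net <- build_network(m, threshold = 0.9), "constant")
  expect_false("flat" %in% net$nodes)
})

test_that("null edge frequency matches the analytic Pearson tail at n = 8", {
  set.seed(10)
  n_panels <- 10
  taxa <- 300
  hits <- 0
  for (i in seq_len(n_panels)) {
    m <- matrix(rnorm(taxa * 8), taxa)
    r <- cor(t(m))
    hits <- hits + sum(abs(r[upper.tri(r)]) >= 0.96)
  }
  n_pairs <- n_panels * choose(taxa, 2)
  expected <- n_pairs * pbeta(0.96^2, 0.5, 3, lower.tail = FALSE)
  expect_gt(hits, 0.5 * expected)
  expect_lt(hits, 1.7 * expected)
})

test_that("topology reports the analytic values for canonical graphs", {
  tri <- igraph::make_full_graph(3)
  tt <- topology(tri)
  expect_equal(tt$density, 1)
  expect_equal(tt$connectedness, 1)
  expect_equal(tt$avg_degree, 2)
  expect_equal(tt$avg_clustering, 1)

  # two disjoint dyads among 4 nodes: 2 reachable pairs of 6
  two_k2 <- igraph::make_graph(c(1, 2, 3, 4), directed = FALSE)
  t2 <- topology(two_k2)
  expect_equal(t2$connectedness, 1 / 3)
  a <- as.matrix(igraph::as_adjacency_matrix(two_k2))
  expect_equal(t2$connectedness, oracle_connectedness(a))

  # two disconnected triangles: the 2-clique partition has Q = 1/2
  two_tri <- igraph::make_graph(c(1, 2, 2, 3, 3, 1, 4, 5, 5, 6, 6, 4),
                                directed = FALSE)
  t3 <- topology(two_tri)
  expect_equal(t3$modularity, 0.5)
  expect_equal(t3$n_modules, 2)
  expect_equal(t3$connectedness, oracle_connectedness(
    as.matrix(igraph::as_adjacency_matrix(two_tri))))

  edgeless <- igraph::make_empty_graph(10, directed = FALSE)
  te <- topology(edgeless)
  expect_equal(te$connectedness, 0)
  expect_equal(te$avg_degree, 0)
  expect_true(is.na(te$modularity))
})

test_that("power-law fit is exact on an exact power law and degenerate otherwise", {
  # frequencies 720 / k^2 over k in {1,2,3,4,6,12} are all integers
  ks <- c(1, 2, 3, 4, 6, 12)
  degs <- rep(ks, times = 720 / ks^2)
  fit <- powerlaw_fit(degs)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, -2, tolerance = 1e-12)

  unif <- rep(1:10, each = 5)
  fu <- powerlaw_fit(unif)
  expect_equal(fu$slope, 0, tolerance = 1e-12)
  expect_equal(fu$r_squared, 0, tolerance = 1e-12)

  expect_warning(f2 <- powerlaw_fit(c(1, 1, 2, 2)), "3 distinct")
  expect_true(is.na(f2$r_squared))
})
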