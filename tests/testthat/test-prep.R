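test_that("rarefaction subsamples exactly to depth and reports drops", {
  x <- toy_counts(cbind(c(2L, 0L), c(60L, 40L), c(80L, 20L)))
  res <- rarefy(x, 2, seed = 1)
  expect_true(all(colSums(res$table) == 2))
  expect_identical(res$table[, "s1"], c(t1 = 2L, t2 = 0L))
  expect_equal(nrow(res$dropped), 0)

  # every sample below depth is an explanatory failure
  expect_error(rarefy(toy_counts(cbind(c(60L, 40L))), 150), "depth")

  mixed <- toy_counts(cbind(c(60L, 40L), c(5L, 5L)))
  res3 <- rarefy(mixed, 50, seed = 2)
  expect_equal(res3$dropped$sample_id, "s2")
  expect_equal(res3$dropped$total, 10)
  expect_equal(colnames(res3$table), "s1")
})

test_that("rarefaction matches the hypergeometric expectation", {
  # (60, 40) subsampled to 10 without replacement: E[first taxon] = 6.
  x <- toy_counts(cbind(c(60L, 40L)))
  set.seed(99)
  draws <- replicate(400, rarefy(x, 10)$table[1, 1])
  se <- sqrt(10 * 0.6 * 0.4 * (90 / 99) / 400)
  expect_lt(abs(mean(draws) - 6), 5 * se)
  expect_true(all(draws >= 0 & draws <= 10))
})

test_that("abundance classes use strict thresholds on mean relative abundance", {
  # one sample of 100,000 reads: relative abundances are counts / 1e5
  counts <- c(filler = 99635L, a = 200L, b = 100L, c = 50L, d = 10L, e = 5L)
  x <- toy_counts(matrix(counts, ncol = 1), taxa = names(counts))
  cls <- classify_abundance(x)
  expect_equal(as.character(cls[["a"]]), "abundant")      # 0.2 %
  expect_equal(as.character(cls[["b"]]), "intermediate")  # exactly 0.1 %
  expect_equal(as.character(cls[["c"]]), "intermediate")  # 0.05 %
  expect_equal(as.character(cls[["d"]]), "intermediate")  # exactly 0.01 %
  expect_equal(as.character(cls[["e"]]), "rare")          # 0.005 %
  # invariant to rescaling the whole table
  expect_identical(cls, classify_abundance(x * 3L))
})

test_that("salinity grouping chunks sorted samples with deterministic ties", {
  meta <- data.frame(sample_id = sprintf("S%02d", 1:48),
                     salinity = seq(0.8, 21, length.out = 48))
  g <- assign_salinity_groups(meta, 6)
  expect_equal(g$groups$n, rep(8, 6))
  expect_true(all(diff(g$groups$mean_salinity) > 0))
  expect_equal(sort(unique(g$assignment$group)), sprintf("n%d", 1:6))

  g2 <- assign_salinity_groups(
    data.frame(sample_id = letters[1:6], salinity = 1:6), 2)
  expect_equal(g2$assignment$sample_id[g2$assignment$group == "n1"],
               c("a", "b", "c"))

  # tie at the block boundary resolved by sample ID
  meta_tie <- data.frame(sample_id = c("W", "X", "Y", "Z"),
                         salinity = c(2, 1, 2, 3))
  g3 <- assign_salinity_groups(meta_tie, 2)
  expect_equal(g3$assignment$sample_id[g3$assignment$group == "n1"],
               c("X", "W"))

  expect_error(assign_salinity_groups(
    data.frame(sample_id = letters[1:7], salinity = 1:7), 2), "remainder")
  g4 <- assign_salinity_groups(
    data.frame(sample_id = letters[1:7], salinity = 1:7), 2,
    remainder = "trim")
  expect_equal(nrow(g4$assignment), 6)
  expect_false("g" %in% g4$assignment$sample_id)
})

test_that("prevalence filtering honours the occupancy fraction", {
  x <- toy_counts(rbind(c(1, 1, 1, 1, 1, 1, 1, 0),
                        c(1, 1, 1, 1, 0, 0, 0, 0),
                        c(2, 3, 4, 5, 6, 7, 8, 9)))
  expect_equal(rownames(prevalence_filter(x, min_prevalence = 1)), "t3")
  expect_equal(rownames(prevalence_filter(x, min_prevalence = 0.5)),
               c("t1", "t2", "t3"))
  all_pos <- toy_counts(matrix(1L, 3, 4))
  expect_identical(prevalence_filter(all_pos, min_prevalence = 1), all_pos)
  expect_error(prevalence_filter(x, min_prevalence = 0), "min_prevalence")
})

test_that("CLR transform matches its closed form and sums to zero", {
  x1 <- toy_counts(matrix(c(1, 1, 1, 1), ncol = 1))
  expect_equal(unname(clr_transform(x1, 0)[, 1]), rep(0, 4))

  e <- exp(1)
  x2 <- matrix(round(c(1, e, e^2, e^3) * 1e6), ncol = 1)
  x2 <- toy_counts(x2)
  expect_equal(unname(clr_transform(x2, 0)[, 1]),
               c(-1.5, -0.5, 0.5, 1.5), tolerance = 1e-5)

  set.seed(1)
  x3 <- toy_counts(matrix(rpois(40, 20) + 1L, 8, 5))
  out <- clr_transform(x3, 0)
  expect_true(all(abs(colSums(out)) < 1e-10))
  # location-free: a per-sample multiplicative constant cancels
  expect_equal(clr_transform(x3 * 7L, 0), out)

  with_zero <- toy_counts(matrix(c(0L, 1L, 2L, 3L), 2))
  expect_error(clr_transform(with_zero, 0), "pseudocount")
  expect_silent(clr_transform(with_zero))  # auto pseudocount 1
})
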