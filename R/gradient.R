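#' Correlation between geographic distance and an environmental variable
#'
#' For the sites of one transect, computes great-circle (haversine, mean
#' Earth radius 6371 km) distances between all site pairs and the absolute
#' pairwise differences of an environmental variable, and reports their
#' Pearson correlation. Used to establish which physicochemical variable
#' tracks the river-to-sea gradient.
#'
#' @param meta Data frame with `latitude`, `longitude` and the variable
#'   column, one row per site (a single transect).
#' @param variable Name of the variable column.
#' @return List with `r`, `p_value`, `n_pairs` and `undefined` (TRUE when
#'   the variable is constant, in which case `r` is `NA`).
#' @export
geo_env_correlation <- function(meta, variable) {
  stopifnot(is.data.frame(meta),
            all(c("latitude", "longitude", variable) %in% names(meta)))
  if (nrow(meta) < 3) stop("need at least 3 sites")
  v <- meta[[variable]]
  dm <- geosphere::distm(cbind(meta$longitude, meta$latitude),
                         fun = function(p1, p2)
                           geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  iu <- upper.tri(dm)
  dd <- dm[iu]
  dv <- abs(outer(v, v, "-"))[iu]
  if (stats::sd(dv) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n_pairs = length(dd),
                undefined = TRUE))
  ct <- stats::cor.test(dd, dv)
  list(r = unname(ct$estimate), p_value = ct$p.value, n_pairs = length(dd),
       undefined = FALSE)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation between the condensed upper triangles, with a
#' permutation p-value: rows and columns of `d2` are permuted jointly and
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)` (one-sided).
#'
#' @param d1,d2 Symmetric distance matrices (or `dist` objects) in the same
#'   sample order.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return A `mantel_result` list with `r`, `p_value`, `n_permutations`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!isTRUE(all.equal(dim(m1), dim(m2))))
    stop("distance matrices differ in size")
  n <- nrow(m1)
  if (n < 4) stop("need at least 4 observations")
  if (max(abs(m1 - t(m1))) > 1e-10 || max(abs(m2 - t(m2))) > 1e-10)
    stop("distance matrices must be symmetric")
  if (any(abs(diag(m1)) > 1e-12) || any(abs(diag(m2)) > 1e-12))
    stop("distance matrices must have zero diagonals")
  if (!is.null(seed)) set.seed(seed)
  iu <- upper.tri(m1)
  v1 <- m1[iu]
  r_obs <- stats::cor(v1, m2[iu])
  hits <- 0L
  for (k in seq_len(n_perm)) {
    p <- sample.int(n)
    if (stats::cor(v1, m2[p, p][iu]) >= r_obs) hits <- hits + 1L
  }
  structure(list(r = r_obs, p_value = (1 + hits) / (1 + n_perm),
                 n_permutations = n_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f, p = %.4g (%d permutations)\n",
              x$r, x$p_value, x$n_permutations))
  invisible(x)
}

#' Per-sample alpha diversity
#'
#' @param x Taxa-by-samples count matrix (rarefied).
#' @param metric `"richness"` (observed taxa) or `"shannon"`
#'   (natural-log Shannon index).
#' @return Named numeric vector over samples.
#' @export
alpha_diversity <- function(x, metric = c("richness", "shannon")) {
  check_abundance(x)
  metric <- match.arg(metric)
  if (any(colSums(x) == 0)) stop("empty sample(s)")
  if (metric == "richness") colSums(x > 0)
  else vegan::diversity(t(x), index = "shannon")
}

#' Ordinary least-squares trend
#'
#' The workhorse behind every "quantity versus salinity" regression:
#' fits `y ~ x`, reporting slope, intercept, R-squared and the two-sided
#' slope p-value.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, `x` non-constant).
#' @return A `trend_result` list: slope, intercept, r_squared, p_value, n.
#' @export
linear_trend <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("x is constant; trend undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- stats::coef(sm)
  structure(list(slope = co["x", "Estimate"],
                 intercept = co["(Intercept)", "Estimate"],
                 r_squared = sm$r.squared,
                 p_value = if (nrow(co) > 1) co["x", "Pr(>|t|)"] else NA_real_,
                 n = n),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("trend: slope = %.4g, R2 = %.3f, p = %.4g, n = %d\n",
              x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Bray-Curtis community distance
#'
#' Convenience wrapper computing Bray-Curtis dissimilarities between the
#' samples of a count table on relative abundances, the community-distance
#' convention used for the Mantel tests.
#'
#' @param x Taxa-by-samples count matrix.
#' @return A `dist` over samples.
#' @export
community_distance <- function(x) {
  check_abundance(x)
  vegan::vegdist(t(rel_abundance(x)), method = "bray")
}

#' Euclidean environmental distance on z-scored variables
#'
#' @param meta Sample metadata.
#' @param variables Character vector of metadata columns.
#' @return A `dist` over samples.
#' @export
environment_distance <- function(meta, variables) {
  stopifnot(all(variables %in% names(meta)))
  z <- scale(as.matrix(meta[, variables, drop = FALSE]))
  stats::dist(z)
}
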