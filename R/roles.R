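#' Relative degree of every node in a network
#'
#' Relative degree -- a node's degree divided by its network's average
#' degree -- makes node importance comparable across networks of different
#' size and density. By construction the mean relative degree over a
#' network's nodes is exactly 1.
#'
#' @param net A `cooc_network` (or igraph graph) with at least one edge.
#' @param classes Optional named abundance classes over the taxon universe;
#'   joined onto the records when given.
#' @return Data frame of role records: network_id, group_salinity, taxon,
#'   degree, relative_degree, abundance_class.
#' @export
relative_degree <- function(net, classes = NULL) {
  g <- as_igraph(net)
  if (igraph::vcount(g) == 0) stop("empty network")
  deg <- igraph::degree(g)
  avg <- mean(deg)
  if (avg == 0) stop("edgeless network: relative degree undefined")
  taxa <- igraph::V(g)$name %||% as.character(seq_along(deg))
  cls <- if (is.null(classes)) factor(rep(NA, length(taxa)),
                                      levels = abundance_class_levels)
  else factor(as.character(classes[taxa]), levels = abundance_class_levels)
  data.frame(network_id = (if (inherits(net, "cooc_network"))
    net$group_id %||% NA_character_ else NA_character_),
    group_salinity = if (inherits(net, "cooc_network"))
      net$group_salinity else NA_real_,
    taxon = taxa, degree = unname(deg),
    relative_degree = unname(deg) / avg,
    abundance_class = cls,
    stringsAsFactors = FALSE)
}

#' Abundant-minus-rare gap in relative degree
#'
#' @param records Role records of one network (from [relative_degree()]).
#' @return List with `mean_abundant`, `mean_rare`, `difference` and
#'   `defined` (FALSE, with `NA` difference, when a class is absent).
#' @export
class_gap <- function(records) {
  a <- records$relative_degree[records$abundance_class == "abundant"]
  r <- records$relative_degree[records$abundance_class == "rare"]
  a <- a[!is.na(a)]; r <- r[!is.na(r)]
  if (length(a) == 0 || length(r) == 0)
    return(list(mean_abundant = if (length(a)) mean(a) else NA_real_,
                mean_rare = if (length(r)) mean(r) else NA_real_,
                difference = NA_real_, defined = FALSE))
  list(mean_abundant = mean(a), mean_rare = mean(r),
       difference = mean(a) - mean(r), defined = TRUE)
}

#' Freeman's theta ordinal effect size
#'
#' Over all cross-pairs between two groups of values, counts concordances
#' `P = #(a > b)` and discordances `Q = #(a < b)` (ties count for neither)
#' and returns `|P - Q| / (n_a * n_b)`, an effect size in `[0, 1]`: 1 under
#' complete separation, 0 when the groups are exchangeable.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return Theta in `[0, 1]`.
#' @export
freeman_theta <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  d <- outer(a, b, "-")
  abs(sum(d > 0) - sum(d < 0)) / (length(a) * length(b))
}

#' Trends of biosphere roles across the gradient
#'
#' Pools role records over networks and fits four regressions against
#' salinity: node-level relative degree of abundant taxa, node-level
#' relative degree of rare taxa (each node carrying its network's mean
#' salinity), the per-network abundant-minus-rare gap, and the per-network
#' Freeman's theta between abundant and rare relative degrees.
#'
#' @param records_list List of per-network role-record data frames (>= 3),
#'   each with `group_salinity` set.
#' @param salinities Optional override of per-network salinities.
#' @return List with `abundant_rd`, `rare_rd`, `class_gap`, `theta` (each a
#'   `trend_result`) and `per_network` (data frame: network_id, salinity,
#'   gap, theta).
#' @export
role_trends <- function(records_list, salinities = NULL) {
  if (length(records_list) < 3) stop("need at least 3 networks")
  if (is.null(salinities))
    salinities <- vapply(records_list,
                         function(r) r$group_salinity[1], numeric(1))
  stopifnot(length(salinities) == length(records_list))
  per <- data.frame(network_id = vapply(records_list, function(r)
    as.character(r$network_id[1]), character(1)),
    salinity = salinities, gap = NA_real_, theta = NA_real_,
    stringsAsFactors = FALSE)
  pooled <- do.call(rbind, Map(function(r, s) {
    r$group_salinity <- s; r
  }, records_list, salinities))
  for (i in seq_along(records_list)) {
    r <- records_list[[i]]
    g <- class_gap(r)
    per$gap[i] <- g$difference
    if (g$defined) {
      a <- r$relative_degree[r$abundance_class == "abundant"]
      b <- r$relative_degree[r$abundance_class == "rare"]
      per$theta[i] <- freeman_theta(a, b)
    }
  }
  if (anyNA(per$gap))
    warning("abundant or rare class absent in some network(s); those networks are dropped from the gap and theta trends")
  na_trend <- structure(list(slope = NA_real_, intercept = NA_real_,
                             r_squared = NA_real_, p_value = NA_real_,
                             n = 0L), class = "trend_result")
  safe_trend <- function(x, y) tryCatch(linear_trend(x, y),
                                        error = function(e) na_trend)
  trend_for <- function(class) {
    sub <- pooled[pooled$abundance_class == class &
                    !is.na(pooled$abundance_class), ]
    safe_trend(sub$group_salinity, sub$relative_degree)
  }
  ok <- !is.na(per$gap)
  list(abundant_rd = trend_for("abundant"),
       rare_rd = trend_for("rare"),
       class_gap = safe_trend(per$salinity[ok], per$gap[ok]),
       theta = safe_trend(per$salinity[ok], per$theta[ok]),
       per_network = per)
}

#' Levins niche breadth per taxon
#'
#' For taxon i with occupancy proportions `p_ij` (the taxon's counts
#' normalised by its own total across samples), Levins' breadth is
#' `B_i = 1 / sum_j p_ij^2`, ranging from 1 (all reads in one sample) to
#' the number of samples (perfectly even occupancy). The standardised form
#' `(B - 1) / (n_samples - 1)` lies in `[0, 1]`. All-zero taxa are excluded
#' with a warning.
#'
#' @param x Taxa-by-samples count matrix.
#' @param classes Optional named abundance classes to join.
#' @return Data frame: taxon, levins_B, standardized_BA, abundance_class.
#' @export
levins_breadth <- function(x, classes = NULL) {
  check_abundance(x)
  tot <- rowSums(x)
  if (any(tot == 0)) {
    warning(sprintf("excluding %d all-zero taxa", sum(tot == 0)))
    x <- x[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  p <- x / tot
  b <- 1 / rowSums(p^2)
  cls <- if (is.null(classes)) factor(rep(NA, nrow(x)),
                                      levels = abundance_class_levels)
  else factor(as.character(classes[rownames(x)]),
              levels = abundance_class_levels)
  data.frame(taxon = rownames(x), levins_B = unname(b),
             standardized_BA = unname((b - 1) / (ncol(x) - 1)),
             abundance_class = cls, stringsAsFactors = FALSE)
}

#' Compare niche breadths of abundant and rare taxa
#'
#' Two-sided Wilcoxon rank-sum test on the Levins breadth values of the
#' abundant versus the rare biosphere (exact small-sample distribution
#' where applicable, per [stats::wilcox.test()]).
#'
#' @param records Output of [levins_breadth()] with classes joined.
#' @return List with `statistic`, `p_value`, `n_abundant`, `n_rare`.
#' @export
breadth_comparison <- function(records) {
  a <- records$levins_B[records$abundance_class == "abundant"]
  r <- records$levins_B[records$abundance_class == "rare"]
  a <- a[!is.na(a)]; r <- r[!is.na(r)]
  if (length(a) == 0 || length(r) == 0)
    stop("both abundant and rare classes must be represented")
  w <- stats::wilcox.test(a, r, alternative = "two.sided", exact = NULL)
  list(statistic = unname(w$statistic), p_value = w$p.value,
       n_abundant = length(a), n_rare = length(r))
}
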