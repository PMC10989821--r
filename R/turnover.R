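#' Describe a network community
#'
#' A network community is the set of taxa constituting one salinity group's
#' co-occurrence network (distinct from the modules inside it), carrying
#' each member's abundance class and its mean relative abundance over that
#' group's own samples.
#'
#' @param net A `cooc_network`.
#' @param classes Named factor/character of abundance classes over the
#'   taxon universe (see [classify_abundance()]).
#' @param abundance Named numeric of mean relative abundances over the
#'   taxon universe (typically computed within the network's sample
#'   group).
#' @return A `network_community` list: `id`, `salinity`, `nodes`,
#'   `classes`, `abundance` (all restricted to member taxa).
#' @export
network_community <- function(net, classes, abundance) {
  stopifnot(inherits(net, "cooc_network"))
  nodes <- net$nodes
  missing_cls <- setdiff(nodes, names(classes))
  missing_ab <- setdiff(nodes, names(abundance))
  if (length(missing_cls) || length(missing_ab))
    stop("classes/abundance must cover every network node")
  structure(list(id = net$group_id, salinity = net$group_salinity,
                 nodes = nodes,
                 classes = factor(as.character(classes[nodes]),
                                  levels = abundance_class_levels),
                 abundance = abundance[nodes]),
            class = "network_community")
}

class_proportions <- function(cls) {
  if (length(cls) == 0) return(NULL)
  tab <- table(factor(cls, levels = abundance_class_levels))
  p <- as.numeric(tab) / length(cls)
  names(p) <- abundance_class_levels
  p
}

#' Overlap between two network communities
#'
#' Splits the two node sets into shared and unique taxa and reports, within
#' each set, the proportion of taxa per abundance class (NULL when a set is
#' empty).
#'
#' @param c1,c2 `network_community` objects over the same taxon universe.
#' @return List with `overlap`, `unique_1`, `unique_2` (character vectors)
#'   and `proportions` (a list of per-set class proportions).
#' @export
community_overlap <- function(c1, c2) {
  stopifnot(inherits(c1, "network_community"),
            inherits(c2, "network_community"))
  ov <- intersect(c1$nodes, c2$nodes)
  u1 <- setdiff(c1$nodes, c2$nodes)
  u2 <- setdiff(c2$nodes, c1$nodes)
  cls1 <- stats::setNames(c1$classes, c1$nodes)
  cls2 <- stats::setNames(c2$classes, c2$nodes)
  list(overlap = ov, unique_1 = u1, unique_2 = u2,
       proportions = list(overlap = class_proportions(cls1[ov]),
                          unique_1 = class_proportions(cls1[u1]),
                          unique_2 = class_proportions(cls2[u2])))
}

#' Bray-Curtis similarity between two network communities
#'
#' One minus the Bray-Curtis distance between the communities'
#' mean-relative-abundance vectors over the union of their member taxa
#' (non-members contribute zero). `mode = "presence"` replaces abundances
#' with 0/1 membership.
#'
#' @param c1,c2 `network_community` objects.
#' @param mode `"abundance"` (default) or `"presence"`.
#' @return Similarity in `[0, 1]`.
#' @export
community_similarity <- function(c1, c2,
                                 mode = c("abundance", "presence")) {
  mode <- match.arg(mode)
  stopifnot(inherits(c1, "network_community"),
            inherits(c2, "network_community"))
  uni <- union(c1$nodes, c2$nodes)
  u <- stats::setNames(numeric(length(uni)), uni)
  v <- u
  if (mode == "abundance") {
    u[c1$nodes] <- c1$abundance
    v[c2$nodes] <- c2$abundance
  } else {
    u[c1$nodes] <- 1
    v[c2$nodes] <- 1
  }
  tot <- sum(u + v)
  if (tot == 0) stop("both communities have zero total abundance")
  1 - sum(abs(u - v)) / tot
}

#' Trend of community similarity with salinity span
#'
#' Over all pairs of networks, regresses pairwise community similarity on
#' the absolute difference of the networks' mean salinities.
#'
#' @param communities List of `network_community` objects (>= 3).
#' @param salinities Mean salinity per community (defaults to the values
#'   stored in the communities).
#' @param mode Passed to [community_similarity()].
#' @return List with `pairs` (data frame: i, j, delta_salinity,
#'   similarity) and `trend` (a `trend_result`).
#' @export
turnover_trend <- function(communities, salinities = NULL,
                           mode = c("abundance", "presence")) {
  mode <- match.arg(mode)
  k <- length(communities)
  if (k < 3) stop("need at least 3 networks")
  if (is.null(salinities))
    salinities <- vapply(communities, `[[`, numeric(1), "salinity")
  stopifnot(length(salinities) == k)
  cmb <- utils::combn(k, 2)
  pairs <- data.frame(i = cmb[1, ], j = cmb[2, ])
  pairs$delta_salinity <- abs(salinities[pairs$i] - salinities[pairs$j])
  pairs$similarity <- mapply(function(i, j)
    community_similarity(communities[[i]], communities[[j]], mode = mode),
    pairs$i, pairs$j)
  list(pairs = pairs,
       trend = linear_trend(pairs$delta_salinity, pairs$similarity))
}
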