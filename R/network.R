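#' Build a co-occurrence network for one salinity group
#'
#' Computes all-pairs Pearson correlations between taxa over the group's
#' CLR-transformed samples and keeps an undirected edge wherever
#' `|r| >= threshold`, recording the correlation and its sign. Taxa whose
#' CLR vector is constant are excluded with a warning (their correlations
#' are undefined); taxa left without any edge are excluded from the node
#' set.
#'
#' @param clr Taxa-by-samples numeric matrix (one group's CLR values).
#' @param threshold Uniform correlation threshold in (0, 1] (default 0.96).
#' @param group_salinity Mean salinity of the group (stored on the
#'   network).
#' @param group_id Optional group label.
#' @return A `cooc_network`: list with `graph` (igraph, edge attributes
#'   `r` and `sign`), `edges` (data frame), `nodes`, `threshold`,
#'   `group_salinity`, `group_id`, `n_taxa_considered`.
#' @export
build_network <- function(clr, threshold = 0.96, group_salinity = NA_real_,
                          group_id = NULL) {
  stopifnot(is.matrix(clr), is.numeric(clr))
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  if (ncol(clr) < 4) stop("need at least 4 samples in the group")
  if (nrow(clr) < 2) stop("need at least 2 taxa")
  if (is.null(rownames(clr))) stop("clr must carry taxon rownames")
  sds <- apply(clr, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding %d taxa with constant CLR vectors",
                    sum(sds == 0)))
    clr <- clr[sds > 0, , drop = FALSE]
    if (nrow(clr) < 2) stop("fewer than 2 non-constant taxa remain")
  }
  r_mat <- stats::cor(t(clr))
  hit <- which(abs(r_mat) >= threshold & upper.tri(r_mat), arr.ind = TRUE)
  edges <- data.frame(from = rownames(clr)[hit[, 1]],
                      to = rownames(clr)[hit[, 2]],
                      r = r_mat[hit],
                      stringsAsFactors = FALSE)
  edges$sign <- ifelse(edges$r > 0, 1L, -1L)
  nodes <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(graph = g, edges = edges, nodes = nodes,
                 threshold = threshold, group_salinity = group_salinity,
                 group_id = group_id, n_taxa_considered = nrow(clr)),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("cooc_network%s: %d nodes, %d edges (|r| >= %.2f, salinity %.2f)\n",
              if (is.null(x$group_id)) "" else paste0(" ", x$group_id),
              length(x$nodes), nrow(x$edges), x$threshold, x$group_salinity))
  invisible(x)
}

# Coerce a cooc_network, igraph or adjacency matrix to an igraph graph.
as_igraph <- function(x) {
  if (inherits(x, "cooc_network")) return(x$graph)
  if (inherits(x, "igraph")) return(x)
  if (is.matrix(x))
    return(igraph::graph_from_adjacency_matrix(x != 0, mode = "undirected"))
  stop("cannot interpret `x` as a graph")
}

#' Topological properties of a co-occurrence network
#'
#' Reports the standard summary of an ecological network: node and link
#' counts, average degree, average local clustering (nodes of degree < 2
#' contribute 0), density, Krackhardt connectedness (the fraction of node
#' pairs joined by some path: 0 for a graph without links, 1 for a
#' connected graph), modularity and module count from greedy (CNM)
#' modularity maximisation, and the R-squared of the log-log power-law fit
#' to the degree distribution.
#'
#' @param x A `cooc_network`, igraph graph, or adjacency matrix.
#' @return One-row data frame: n_nodes, n_links, avg_degree,
#'   avg_clustering, density, connectedness, modularity, n_modules,
#'   powerlaw_r_squared.
#' @export
topology <- function(x) {
  g <- as_igraph(x)
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph")
  l <- igraph::ecount(g)
  deg <- igraph::degree(g)
  avg_clust <- if (n == 1) 0 else
    igraph::transitivity(g, type = "localaverage", isolates = "zero")
  comp <- igraph::components(g)$csize
  connectedness <- if (n < 2) NA_real_ else
    sum(choose(comp, 2)) / choose(n, 2)
  if (l > 0) {
    cl <- igraph::cluster_fast_greedy(g)
    q <- igraph::modularity(cl)
    n_mod <- length(cl)
  } else {
    q <- NA_real_
    n_mod <- NA_integer_
  }
  pl <- powerlaw_fit(deg)
  data.frame(n_nodes = n, n_links = l, avg_degree = 2 * l / n,
             avg_clustering = avg_clust,
             density = if (n < 2) NA_real_ else 2 * l / (n * (n - 1)),
             connectedness = connectedness, modularity = q,
             n_modules = n_mod, powerlaw_r_squared = pl$r_squared)
}

#' Power-law fit to a degree distribution
#'
#' Ordinary least squares of `log(frequency)` on `log(degree)` over the
#' observed positive degrees (unbinned; zero-frequency degrees skipped).
#' At least 3 distinct positive degrees are required, otherwise the fit is
#' undefined and `NA` is returned with a warning.
#'
#' @param degrees Integer vector of node degrees.
#' @return List with `r_squared`, `slope` and `n_distinct`.
#' @export
powerlaw_fit <- function(degrees) {
  d <- degrees[degrees > 0]
  tab <- table(d)
  k <- as.numeric(names(tab))
  if (length(k) < 3) {
    warning("fewer than 3 distinct positive degrees; power-law fit undefined")
    return(list(r_squared = NA_real_, slope = NA_real_,
                n_distinct = length(k)))
  }
  fit <- stats::lm(log(as.numeric(tab)) ~ log(k))
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       n_distinct = length(k))
}
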