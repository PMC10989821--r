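# Unsigned, unweighted dense adjacency matrix of a network.
as_adjacency_dense <- function(x) {
  if (is.matrix(x) && is.numeric(x)) {
    if (nrow(x) != ncol(x) || max(abs(x - t(x))) > 0)
      stop("adjacency matrix must be square and symmetric")
    return((x != 0) * 1)
  }
  g <- as_igraph(x)
  as.matrix(igraph::as_adjacency_matrix(g, type = "both", sparse = FALSE)) > 0
}

#' Natural connectivity of a graph
#'
#' The spectral robustness index
#' `ln((1/N) * sum_i exp(lambda_i))` over the eigenvalues of the unsigned,
#' unweighted adjacency matrix; it equals the log of the average closed-walk
#' generating value (Estrada index / N) and is 0 for an edgeless graph.
#' Eigenvalues come from a symmetric eigendecomposition; the largest
#' eigenvalue is factored out before exponentiation for numerical
#' stability.
#'
#' @param x A `cooc_network`, igraph graph, or (symmetric 0/1) adjacency
#'   matrix; the graph may be disconnected.
#' @return The natural connectivity (non-negative scalar).
#' @export
natural_connectivity <- function(x) {
  a <- as_adjacency_dense(x) * 1
  n <- nrow(a)
  if (n < 1) stop("empty graph")
  if (n == 1) return(0)
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  m <- max(ev)
  m + log(mean(exp(ev - m)))
}

#' Random node-removal stability simulation
#'
#' Simulates species extinction: for each removal fraction `p`,
#' `round(p * N)` nodes are removed uniformly at random and the average
#' degree and natural connectivity of the induced subgraph are recorded
#' (surviving isolated nodes stay in the node set for both indices).
#'
#' @param net A `cooc_network`, igraph graph, or adjacency matrix.
#' @param fractions Removal fractions in `[0, 1)`.
#' @param n_replicates Replicates per fraction (default 100).
#' @param seed Optional integer seed.
#' @return A `robustness_result` list with `values` (fraction, replicate,
#'   avg_degree, natural_connectivity), `summary` (per-fraction mean and
#'   SD of both indices), `n_replicates` and `seed`.
#' @export
removal_simulation <- function(net, fractions = seq(0.05, 0.5, by = 0.05),
                               n_replicates = 100, seed = NULL) {
  a <- as_adjacency_dense(net) * 1
  n <- nrow(a)
  if (any(fractions < 0 | fractions >= 1))
    stop("fractions must lie in [0, 1)")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (any(round(fractions * n) >= n))
    stop("a fraction would remove every node")
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", length(fractions) * n_replicates)
  idx <- 0L
  for (p in fractions) {
    k <- round(p * n)
    for (rep_i in seq_len(n_replicates)) {
      keep <- if (k == 0) seq_len(n) else
        sort(sample.int(n, n - k))
      sub <- a[keep, keep, drop = FALSE]
      idx <- idx + 1L
      rows[[idx]] <- data.frame(fraction = p, replicate = rep_i,
                                avg_degree = mean(rowSums(sub)),
                                natural_connectivity =
                                  natural_connectivity(sub))
    }
  }
  values <- do.call(rbind, rows)
  agg <- function(f) stats::aggregate(
    cbind(avg_degree, natural_connectivity) ~ fraction, values, f)
  mns <- agg(mean); sds <- agg(stats::sd)
  summary_df <- data.frame(fraction = mns$fraction,
                           avg_degree_mean = mns$avg_degree,
                           avg_degree_sd = sds$avg_degree,
                           natural_connectivity_mean =
                             mns$natural_connectivity,
                           natural_connectivity_sd =
                             sds$natural_connectivity)
  structure(list(values = values, summary = summary_df,
                 n_replicates = n_replicates, fractions = fractions,
                 seed = seed),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("robustness_result: %d fractions x %d replicates\n",
              length(x$fractions), x$n_replicates))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Trend of network robustness across the gradient
#'
#' At a fixed removal fraction, regresses the per-network mean of a
#' robustness index on the networks' mean salinities.
#'
#' @param results List of `robustness_result`s (>= 3), one per network.
#' @param salinities Mean salinity per network.
#' @param fraction The removal fraction to compare at (must be present in
#'   every result).
#' @param index `"natural_connectivity"` or `"avg_degree"`.
#' @return A `trend_result`.
#' @export
stability_trend <- function(results, salinities, fraction,
                            index = c("natural_connectivity",
                                      "avg_degree")) {
  index <- match.arg(index)
  if (length(results) < 3) stop("need at least 3 networks")
  if (length(results) != length(salinities))
    stop("results and salinities differ in length")
  vals <- vapply(results, function(r) {
    stopifnot(inherits(r, "robustness_result"))
    i <- which(abs(r$summary$fraction - fraction) < 1e-9)
    if (length(i) != 1)
      stop(sprintf("fraction %.3f missing from a robustness result", fraction))
    r$summary[[paste0(index, "_mean")]][i]
  }, numeric(1))
  linear_trend(salinities, vals)
}
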