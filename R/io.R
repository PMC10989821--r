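#' Read a taxa-by-samples abundance table from TSV
#'
#' Expects a header row of sample IDs and a first column of taxon IDs.
#' Ragged rows, duplicate IDs and negative or non-integer counts are
#' rejected with the offending line reported.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix with taxon rownames and sample colnames.
#' @export
read_abundance_tsv <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1)
    stop(sprintf("ragged TSV: line %d has %d fields (expected %d)",
                 which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1]))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("abundance TSV needs a taxon column and >= 1 sample")
  taxa <- df[[1]]
  if (anyDuplicated(taxa)) {
    i <- which(duplicated(taxa))[1]
    stop(sprintf("duplicate taxon ID %s at line %d", taxa[i], i + 1))
  }
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop(sprintf("duplicate sample ID %s in header",
                 samples[duplicated(samples)][1]))
  vals <- suppressWarnings(vapply(df[-1], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(taxa, samples))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric count at line %d, sample %s",
                 bad[1] + 1, samples[bad[2]]))
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at line %d, sample %s",
                 bad[1] + 1, samples[bad[2]]))
  }
  if (any(vals != round(vals))) {
    bad <- which(vals != round(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at line %d, sample %s",
                 bad[1] + 1, samples[bad[2]]))
  }
  storage.mode(vals) <- "integer"
  check_abundance(vals)
  vals
}

#' Write a taxa-by-samples abundance table to TSV
#'
#' @param x Count matrix.
#' @param path Output path.
#' @param id_column Name of the taxon-ID column (default `"taxon"`).
#' @return Invisibly, `path`.
#' @export
write_abundance_tsv <- function(x, path, id_column = "taxon") {
  check_abundance(x)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' @param path TSV with at least `sample_id` and `salinity` columns.
#' @return Data frame.
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (!all(c("sample_id", "salinity") %in% names(df)))
    stop("metadata must contain sample_id and salinity columns")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  df
}

#' Write sample metadata to TSV
#'
#' @param meta Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metadata_tsv <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a co-occurrence network to file
#'
#' Supports GraphML (via igraph, with `salinity` and `threshold` stored as
#' graph attributes and `r`/`sign` as edge attributes) and a plain
#' edge-list TSV with columns source, target, r, sign, preceded by
#' `# key=value` header lines for the graph attributes. Both formats
#' round-trip through [read_network()] with `r` preserved to better than
#' 1e-12.
#'
#' @param net A `cooc_network`.
#' @param path Output path.
#' @param format `"graphml"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "cooc_network"))
  if (format == "graphml") {
    g <- net$graph
    g <- igraph::set_graph_attr(g, "salinity", net$group_salinity)
    g <- igraph::set_graph_attr(g, "threshold", net$threshold)
    g <- igraph::set_graph_attr(g, "group_id", net$group_id %||% "")
    igraph::write_graph(g, path, format = "graphml")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# group_id=%s", net$group_id %||% ""),
                 sprintf("# salinity=%.17g", net$group_salinity),
                 sprintf("# threshold=%.17g", net$threshold),
                 "source\ttarget\tr\tsign"), con)
    if (nrow(net$edges))
      writeLines(sprintf("%s\t%s\t%.17g\t%d", net$edges$from, net$edges$to,
                         net$edges$r, net$edges$sign), con)
  }
  invisible(path)
}

#' Read a co-occurrence network written by [write_network()]
#'
#' @param path Input path.
#' @param format `"graphml"` or `"tsv"`.
#' @return A `cooc_network`.
#' @export
read_network <- function(path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(from = el$from, to = el$to, r = el$r,
                        sign = as.integer(el$sign),
                        stringsAsFactors = FALSE)
    gid <- igraph::graph_attr(g, "group_id")
    structure(list(graph = g, edges = edges,
                   nodes = sort(igraph::V(g)$name),
                   threshold = igraph::graph_attr(g, "threshold"),
                   group_salinity = igraph::graph_attr(g, "salinity"),
                   group_id = if (identical(gid, "")) NULL else gid,
                   n_taxa_considered = NA_integer_),
              class = "cooc_network")
  } else {
    lines <- readLines(path)
    hdr <- grep("^# ", lines, value = TRUE)
    get <- function(key) sub(sprintf("^# %s=", key), "",
                             grep(sprintf("^# %s=", key), hdr, value = TRUE))
    body <- lines[!grepl("^# ", lines)]
    df <- utils::read.delim(text = paste(body, collapse = "\n"),
                            sep = "\t", stringsAsFactors = FALSE)
    edges <- data.frame(from = as.character(df$source),
                        to = as.character(df$target),
                        r = as.numeric(df$r), sign = as.integer(df$sign),
                        stringsAsFactors = FALSE)
    nodes <- sort(unique(c(edges$from, edges$to)))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
    gid <- get("group_id")
    structure(list(graph = g, edges = edges, nodes = nodes,
                   threshold = as.numeric(get("threshold")),
                   group_salinity = as.numeric(get("salinity")),
                   group_id = if (identical(gid, "")) NULL else gid,
                   n_taxa_considered = NA_integer_),
              class = "cooc_network")
  }
}
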