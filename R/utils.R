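# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stream-specific seed from a root seed
#'
#' All stochastic stages of the pipeline draw their seeds from one root seed
#' through this deterministic map, so that a single integer reproduces an
#' entire run while stages remain independently re-runnable. The map is
#' `(seed * 48271 + hash(stream)) mod (2^31 - 1)`, where `hash` is a
#' position-weighted sum of the stream label's character codes.
#'
#' @param seed Integer root seed.
#' @param stream Character label of the consuming stage (e.g. `"rarefy"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

# Validate a taxon-by-sample count matrix: non-negative whole numbers with
# unique row (taxon) and column (sample) names.
check_abundance <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric taxa-by-samples matrix", arg))
  if (anyNA(x)) stop(sprintf("`%s` contains missing values", arg))
  if (any(x < 0)) stop(sprintf("`%s` contains negative counts", arg))
  if (any(abs(x - round(x)) > 1e-8))
    stop(sprintf("`%s` contains non-integer counts", arg))
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(sprintf("`%s` must carry taxon rownames and sample colnames", arg))
  if (anyDuplicated(rownames(x)))
    stop(sprintf("duplicate taxon IDs in `%s`", arg))
  if (anyDuplicated(colnames(x)))
    stop(sprintf("duplicate sample IDs in `%s`", arg))
  invisible(x)
}

# Per-sample relative abundances (columns sum to 1).
rel_abundance <- function(x) {
  tot <- colSums(x)
  if (any(tot == 0)) stop("sample(s) with zero total counts")
  sweep(x, 2, tot, "/")
}

abundance_class_levels <- c("abundant", "intermediate", "rare")
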