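#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads uniformly without replacement to exactly
#' `depth` reads (via [vegan::rrarefy()]); samples whose total falls below
#' the depth are dropped and reported rather than padded.
#'
#' @param x Taxa-by-samples count matrix.
#' @param depth Target reads per sample.
#' @param seed Optional integer seed for the subsampling.
#' @return List with `table` (rarefied matrix, column sums all equal to
#'   `depth`) and `dropped` (data frame of removed samples and their
#'   totals).
#' @export
rarefy <- function(x, depth, seed = NULL) {
  check_abundance(x)
  stopifnot(length(depth) == 1, depth > 0, depth == round(depth))
  if (!is.null(seed)) set.seed(seed)
  totals <- colSums(x)
  low <- totals < depth
  dropped <- data.frame(sample_id = colnames(x)[low],
                        total = unname(totals[low]),
                        stringsAsFactors = FALSE)
  if (all(low))
    stop(sprintf("no sample reaches the rarefaction depth %d (max total %d)",
                 depth, max(totals)))
  kept <- x[, !low, drop = FALSE]
  # vegan warns about "observed counts" heuristics on dense tables; the
  # inputs here are validated integer counts, so that advice is muffled
  rar <- withCallingHandlers(
    t(vegan::rrarefy(t(kept), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(rar) <- "integer"
  list(table = rar, dropped = dropped)
}

#' Classify taxa into abundant, intermediate and rare biospheres
#'
#' Uses the mean (over samples) relative abundance of each taxon: strictly
#' above `abundant_min` is abundant, strictly below `rare_max` is rare, and
#' everything else -- including values exactly on a threshold -- is
#' intermediate. Defaults are 0.1 % and 0.01 %.
#'
#' @param x Taxa-by-samples count matrix (normally the rarefied full table).
#' @param abundant_min,rare_max Mean relative-abundance thresholds
#'   (fractions, not percent).
#' @return A named factor over taxa with levels abundant, intermediate,
#'   rare.
#' @export
classify_abundance <- function(x, abundant_min = 0.001, rare_max = 0.0001) {
  check_abundance(x)
  if (abundant_min <= rare_max || rare_max <= 0)
    stop("thresholds must satisfy abundant_min > rare_max > 0")
  m <- rowMeans(rel_abundance(x))
  # strict inequalities; values numerically on a threshold are intermediate
  tol <- 1e-12
  cls <- ifelse(m - abundant_min > tol, "abundant",
                ifelse(rare_max - m > tol, "rare", "intermediate"))
  out <- factor(cls, levels = abundance_class_levels)
  names(out) <- rownames(x)
  out
}

#' Partition samples into equal salinity-ordered groups
#'
#' Sorts samples by salinity (ties broken by sample ID, lexicographically)
#' and chunks them into `n_groups` consecutive equal blocks, recording each
#' block's mean salinity.
#'
#' @param meta Data frame with columns `sample_id` and `salinity`.
#' @param n_groups Number of groups.
#' @param remainder What to do when the sample count is not divisible by
#'   `n_groups`: `"fail"` (default) or `"trim"` the highest-salinity
#'   remainder.
#' @return A `salinity_groups` list with `assignment` (sample_id, salinity,
#'   group) and `groups` (group, n, mean_salinity), ordered by mean
#'   salinity.
#' @export
assign_salinity_groups <- function(meta, n_groups,
                                   remainder = c("fail", "trim")) {
  remainder <- match.arg(remainder)
  stopifnot(is.data.frame(meta), all(c("sample_id", "salinity") %in% names(meta)),
            n_groups >= 1)
  ord <- meta[order(meta$salinity, meta$sample_id), c("sample_id", "salinity")]
  n <- nrow(ord)
  extra <- n %% n_groups
  if (extra != 0) {
    if (remainder == "fail")
      stop(sprintf("%d samples are not divisible into %d equal groups (remainder %d); use remainder = \"trim\"",
                   n, n_groups, extra))
    ord <- ord[seq_len(n - extra), , drop = FALSE]
    n <- nrow(ord)
  }
  size <- n / n_groups
  ord$group <- sprintf("n%d", rep(seq_len(n_groups), each = size))
  groups <- data.frame(group = sprintf("n%d", seq_len(n_groups)),
                       n = size,
                       mean_salinity = as.numeric(
                         tapply(ord$salinity, ord$group, mean)[
                           sprintf("n%d", seq_len(n_groups))]),
                       stringsAsFactors = FALSE)
  structure(list(assignment = ord, groups = groups, n_groups = n_groups),
            class = "salinity_groups")
}

#' @export
print.salinity_groups <- function(x, ...) {
  cat(sprintf("salinity_groups: %d groups of %d samples\n",
              x$n_groups, x$groups$n[1]))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Filter taxa by within-group prevalence
#'
#' Retains taxa observed (nonzero) in at least
#' `ceiling(min_prevalence * n_samples)` of the given samples. With the
#' default `min_prevalence = 1` only taxa present in every sample survive;
#' 0.5 reproduces the at-least-half-of-samples variant.
#'
#' @param x Taxa-by-samples count matrix.
#' @param sample_ids Samples defining the group (default: all columns).
#' @param min_prevalence Fraction in (0, 1].
#' @return The filtered submatrix over `sample_ids` (possibly zero rows).
#' @export
prevalence_filter <- function(x, sample_ids = colnames(x),
                              min_prevalence = 1) {
  check_abundance(x)
  if (min_prevalence <= 0 || min_prevalence > 1)
    stop("min_prevalence must lie in (0, 1]")
  missing_ids <- setdiff(sample_ids, colnames(x))
  if (length(missing_ids))
    stop("unknown sample IDs: ", paste(missing_ids, collapse = ", "))
  sub <- x[, sample_ids, drop = FALSE]
  need <- ceiling(min_prevalence * ncol(sub))
  keep <- rowSums(sub > 0) >= need
  sub[keep, , drop = FALSE]
}

#' Centred log-ratio transform
#'
#' Per sample, maps counts `x` to `log(x + pseudocount)` centred by the
#' sample's mean log value, so each transformed sample sums to zero. By
#' default the pseudocount is 1 when zeros are present and 0 otherwise;
#' a zero pseudocount with zeros present is an error.
#'
#' @param x Taxa-by-samples count matrix.
#' @param pseudocount Non-negative value added to all counts before the
#'   log; `NULL` (default) chooses 0 or 1 automatically.
#' @return A numeric matrix of the same shape; columns sum to zero.
#' @export
clr_transform <- function(x, pseudocount = NULL) {
  check_abundance(x)
  has_zero <- any(x == 0)
  if (is.null(pseudocount)) pseudocount <- if (has_zero) 1 else 0
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (pseudocount == 0 && has_zero)
    stop("zeros present: a positive pseudocount is required")
  lx <- log(x + pseudocount)
  sweep(lx, 2, colMeans(lx), "-")
}
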