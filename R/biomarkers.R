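#' Rank taxa by random-forest importance for salinity
#'
#' Fits regression forests of taxa (relative abundances) against salinity
#' repeatedly with distinct seeds and averages the permutation importance
#' (percent increase in out-of-bag MSE) over the refits, returning taxa in
#' descending order of mean importance.
#'
#' @param features Samples-by-taxa numeric matrix (e.g. class-level relative
#'   abundances).
#' @param salinity Numeric response, one value per sample.
#' @param n_iterations Number of forest refits to average over (default
#'   1000).
#' @param ntree Trees per forest (default 500).
#' @param seed Optional integer seed.
#' @return Data frame `(taxon, mean_importance)` sorted by descending
#'   importance.
#' @export
rank_biomarkers <- function(features, salinity, n_iterations = 1000,
                            ntree = 500, seed = NULL) {
  features <- as.matrix(features)
  if (ncol(features) < 2) stop("need at least 2 taxa")
  if (nrow(features) < 10) stop("need at least 10 samples")
  if (length(salinity) != nrow(features))
    stop("salinity length must match the number of samples")
  if (stats::sd(salinity) == 0) stop("salinity is constant")
  if (!is.null(seed)) set.seed(seed)
  acc <- numeric(ncol(features))
  for (it in seq_len(n_iterations)) {
    rf <- randomForest::randomForest(x = features, y = salinity,
                                     ntree = ntree, importance = TRUE)
    acc <- acc + randomForest::importance(rf, type = 1)[, 1]
  }
  imp <- acc / n_iterations
  ord <- order(imp, decreasing = TRUE)
  data.frame(taxon = colnames(features)[ord],
             mean_importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Choose the number of biomarkers by repeated cross-validation
#'
#' For an increasing number of top-ranked taxa, estimates the
#' cross-validated mean squared error of a regression forest restricted to
#' those taxa (k-fold, repeated), then selects the smallest count whose mean
#' error is within one standard error of the curve minimum -- the
#' operational reading of "the error curve stabilised".
#'
#' @param features Samples-by-taxa matrix.
#' @param salinity Numeric response.
#' @param ranked_taxa Character vector of taxa in importance order, or the
#'   data frame returned by [rank_biomarkers()].
#' @param folds,repeats Cross-validation design (defaults 10 and 5).
#' @param ntree Trees per forest.
#' @param ns Candidate biomarker counts (default `1:min(25, n_taxa)`).
#' @param seed Optional integer seed.
#' @return List with `cv_error_curve` (n_top, mean_error, se) and
#'   `selected_n`.
#' @export
select_biomarker_count <- function(features, salinity, ranked_taxa,
                                   folds = 10, repeats = 5, ntree = 500,
                                   ns = NULL, seed = NULL) {
  features <- as.matrix(features)
  if (is.data.frame(ranked_taxa)) ranked_taxa <- ranked_taxa$taxon
  stopifnot(all(ranked_taxa %in% colnames(features)))
  n <- nrow(features)
  if (n < folds) stop("fewer samples than folds")
  if (is.null(ns)) ns <- seq_len(min(25, length(ranked_taxa)))
  stopifnot(all(ns >= 1), all(ns <= length(ranked_taxa)))
  if (!is.null(seed)) set.seed(seed)
  errs <- matrix(NA_real_, length(ns), folds * repeats)
  col <- 0L
  for (rep_i in seq_len(repeats)) {
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    for (f in seq_len(folds)) {
      col <- col + 1L
      test <- fold_id == f
      for (k in seq_along(ns)) {
        feats <- ranked_taxa[seq_len(ns[k])]
        rf <- randomForest::randomForest(
          x = features[!test, feats, drop = FALSE], y = salinity[!test],
          ntree = ntree)
        pred <- stats::predict(rf, features[test, feats, drop = FALSE])
        errs[k, col] <- mean((pred - salinity[test])^2)
      }
    }
  }
  mean_err <- rowMeans(errs)
  k_min <- which.min(mean_err)
  se_min <- stats::sd(errs[k_min, ]) / sqrt(ncol(errs))
  selected <- ns[which(mean_err <= mean_err[k_min] + se_min)[1]]
  list(cv_error_curve = data.frame(n_top = ns, mean_error = mean_err,
                                   se = apply(errs, 1, stats::sd) /
                                     sqrt(ncol(errs))),
       selected_n = selected)
}

#' Label biomarkers as low-salinity, high-salinity or complex colonizers
#'
#' Each biomarker's abundance is regressed on salinity; a significantly
#' negative slope marks a low-salinity colonizer, a significantly positive
#' slope a high-salinity colonizer, and anything without a significant
#' monotone trend is a complex colonizer.
#'
#' @param features Samples-by-taxa matrix.
#' @param salinity Numeric response.
#' @param biomarkers Character vector (subset of column names).
#' @param alpha Significance level (default 0.05).
#' @return Named character vector over biomarkers with values
#'   `low_salinity`, `high_salinity`, `complex`.
#' @export
classify_colonizers <- function(features, salinity, biomarkers,
                                alpha = 0.05) {
  features <- as.matrix(features)
  stopifnot(all(biomarkers %in% colnames(features)))
  out <- vapply(biomarkers, function(b) {
    tr <- linear_trend(salinity, features[, b])
    if (!is.na(tr$p_value) && tr$p_value < alpha) {
      if (tr$slope < 0) "low_salinity" else "high_salinity"
    } else "complex"
  }, character(1))
  names(out) <- biomarkers
  out
}
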