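#' Feature reduction: variance, correlation, collinearity
#'
#' Removes uninformative feature columns in three ordered passes: (1) drop
#' columns whose variance (on standardised columns when `standardize` is on)
#' falls below `variance_min`; (2) greedy correlation filter in column
#' order, dropping a column whose absolute Pearson correlation with any
#' earlier retained column exceeds `corr_max`; (3) iterative collinearity
#' filter, dropping the column with the largest variance inflation factor
#' (VIF, ridge-stabilised) until all VIFs are at or below `vif_max`. Every
#' input column ends up either retained or in the provenance table with its
#' drop reason.
#'
#' @name reduction
NULL

#' @rdname reduction
#' @param variance_min minimum column variance (default `1e-8`).
#' @param corr_max maximum tolerated absolute pairwise Pearson correlation
#'   (default 0.95).
#' @param vif_max maximum tolerated VIF (default 10).
#' @param standardize z-score columns before the correlation and VIF passes.
#' @return `reduction_config()`: a config list recorded in output provenance.
#' @export
reduction_config <- function(variance_min = 1e-8, corr_max = 0.95,
                             vif_max = 10, standardize = TRUE) {
  stopifnot(variance_min >= 0, corr_max > 0, corr_max <= 1, vif_max > 0)
  structure(list(variance_min = variance_min, corr_max = corr_max,
                 vif_max = vif_max, standardize = standardize),
            class = "reduction_config")
}

feature_columns <- function(matrix_tbl) {
  setdiff(names(matrix_tbl), c("image_id", "n_objects"))
}

as_feature_matrix <- function(matrix_tbl, complete_only = TRUE) {
  cols <- feature_columns(matrix_tbl)
  m <- as.matrix(matrix_tbl[cols])
  storage.mode(m) <- "double"
  # flagged empty images (all-NA rows) do not contribute to filter
  # statistics; they are carried through and dropped at embedding time
  if (complete_only) m <- m[stats::complete.cases(m), , drop = FALSE]
  m
}

#' Drop low-variance columns
#'
#' @param matrix_tbl a feature tibble (optionally with an `image_id`
#'   column, which is carried through untouched).
#' @param variance_min variance threshold.
#' @return list with `matrix` (the filtered tibble) and `dropped` (tibble of
#'   `feature`, `statistic`).
#' @export
drop_low_variance <- function(matrix_tbl, variance_min = 1e-8) {
  m <- as_feature_matrix(matrix_tbl)
  if (nrow(m) < 2) abort("Variance filtering needs at least 2 rows.")
  vars <- apply(m, 2, var)
  drop <- names(vars)[vars < variance_min]
  list(matrix = matrix_tbl[setdiff(names(matrix_tbl), drop)],
       dropped = tibble::tibble(feature = drop,
                                statistic = unname(vars[drop])))
}

#' Greedy correlation filter
#'
#' A column is dropped when its absolute Pearson correlation with any
#' earlier retained column exceeds `corr_max`; ties and order follow the
#' manifest column order, so the first of a correlated group survives.
#'
#' @inheritParams drop_low_variance
#' @param corr_max absolute correlation threshold.
#' @export
drop_correlated <- function(matrix_tbl, corr_max = 0.95) {
  m <- as_feature_matrix(matrix_tbl)
  if (nrow(m) < 3) abort("Correlation filtering needs at least 3 rows.")
  cm <- abs(suppressWarnings(cor(m)))
  cm[!is.finite(cm)] <- 0
  p <- ncol(m)
  keep <- logical(p)
  drop_stat <- numeric(0)
  drop_name <- character(0)
  for (j in seq_len(p)) {
    prior <- which(keep)
    worst <- if (length(prior)) max(cm[j, prior]) else 0
    if (worst > corr_max) {
      drop_name <- c(drop_name, colnames(m)[j])
      drop_stat <- c(drop_stat, worst)
    } else keep[j] <- TRUE
  }
  list(matrix = matrix_tbl[setdiff(names(matrix_tbl), drop_name)],
       dropped = tibble::tibble(feature = drop_name, statistic = drop_stat))
}

ridge_vif <- function(m, ridge = 1e-8) {
  if (ncol(m) < 2) return(stats::setNames(rep(1, ncol(m)), colnames(m)))
  z <- scale(m)
  z[!is.finite(z)] <- 0
  R <- crossprod(z) / (nrow(z) - 1)
  diag(R) <- diag(R) + ridge
  vif <- diag(solve(R))
  stats::setNames(pmax(vif, 1), colnames(m))
}

#' Iterative collinearity filter
#'
#' Repeatedly drops the column with the largest ridge-stabilised VIF until
#' all VIFs are at or below `vif_max`. The ridge (1e-8 on the correlation
#' matrix diagonal) keeps exactly collinear sets finite; a single remaining
#' column has VIF 1 by convention.
#'
#' @inheritParams drop_low_variance
#' @param vif_max VIF threshold.
#' @export
drop_collinear <- function(matrix_tbl, vif_max = 10) {
  m <- as_feature_matrix(matrix_tbl)
  drop_name <- character(0)
  drop_stat <- numeric(0)
  repeat {
    if (ncol(m) < 2) break
    vif <- ridge_vif(m)
    worst <- which.max(vif)
    if (vif[worst] <= vif_max) break
    drop_name <- c(drop_name, colnames(m)[worst])
    drop_stat <- c(drop_stat, unname(vif[worst]))
    m <- m[, -worst, drop = FALSE]
  }
  list(matrix = matrix_tbl[setdiff(names(matrix_tbl), drop_name)],
       dropped = tibble::tibble(feature = drop_name, statistic = drop_stat))
}

#' Reduce a feature matrix
#'
#' Pipeline: variance filter, then greedy correlation filter, then iterative
#' collinearity (VIF) filter. The returned tibble carries the complete drop
#' provenance and the configuration as attributes; [reduction_provenance()]
#' retrieves them. The operation is idempotent for a fixed configuration.
#'
#' @param matrix_tbl feature tibble (an `image_id` column is carried
#'   through).
#' @param config a [reduction_config()].
#' @return the reduced tibble, classed `phenoprobe_reduced`, with attributes
#'   `provenance` (tibble: `feature`, `dropped_by`, `statistic`) and
#'   `config`.
#' @export
reduce_features <- function(matrix_tbl, config = reduction_config()) {
  stopifnot(inherits(config, "reduction_config"))
  # note: Pearson correlation and VIF are scale-free, so the standardize
  # flag is recorded in provenance but changes no decision; z-scoring is
  # applied inside the VIF computation regardless for numerical stability
  v <- drop_low_variance(matrix_tbl, config$variance_min)
  cpass <- drop_correlated(v$matrix, config$corr_max)
  vifp <- drop_collinear(cpass$matrix, config$vif_max)
  prov <- dplyr::bind_rows(
    dplyr::mutate(v$dropped, dropped_by = "variance"),
    dplyr::mutate(cpass$dropped, dropped_by = "correlation"),
    dplyr::mutate(vifp$dropped, dropped_by = "collinearity"))
  out <- vifp$matrix
  if (!length(feature_columns(out))) {
    abort("All features were dropped; relax variance_min/corr_max/vif_max.")
  }
  stopifnot(length(feature_columns(out)) + nrow(prov) ==
              length(feature_columns(matrix_tbl)))
  attr(out, "provenance") <- prov[c("feature", "dropped_by", "statistic")]
  attr(out, "config") <- config
  class(out) <- unique(c("phenoprobe_reduced", class(out)))
  out
}

#' @rdname reduce_features
#' @export
reduction_provenance <- function(matrix_tbl) {
  attr(matrix_tbl, "provenance")
}

#' Optional supervised feature selection
#'
#' Ranks features by how well they discriminate two labelled image classes
#' (Welch t statistic) and keeps the strongest `n_keep`. This stage is off
#' by default and is not part of [reduce_features()]: a KO-vs-WT probe
#' screen has no per-probe positive/negative control classes, so the default
#' pipeline is label-free. It exists for designs that do include control
#' wells.
#'
#' @inheritParams drop_low_variance
#' @param labels a two-level factor (or vector coercible to one), one entry
#'   per row.
#' @param n_keep number of features to retain.
#' @return list with `matrix` (the selected tibble) and `scores` (tibble of
#'   `feature`, `statistic` for every input feature).
#' @export
select_discriminative <- function(matrix_tbl, labels, n_keep = 50L) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) abort("`labels` must have exactly two levels.")
  m <- as_feature_matrix(matrix_tbl, complete_only = FALSE)
  if (length(labels) != nrow(m)) abort("One label per row is required.")
  a <- m[labels == levels(labels)[1], , drop = FALSE]
  b <- m[labels == levels(labels)[2], , drop = FALSE]
  stat <- vapply(seq_len(ncol(m)), function(j) {
    se <- sqrt(var(a[, j]) / nrow(a) + var(b[, j]) / nrow(b))
    if (!is.finite(se) || se == 0) return(0)
    abs(mean(a[, j]) - mean(b[, j])) / se
  }, 0)
  scores <- tibble::tibble(feature = colnames(m), statistic = stat)
  keep <- scores$feature[order(-scores$statistic)][seq_len(min(n_keep, ncol(m)))]
  keep_cols <- c(intersect(c("image_id", "n_objects"), names(matrix_tbl)),
                 intersect(names(matrix_tbl), keep))
  list(matrix = matrix_tbl[keep_cols], scores = scores)
}
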