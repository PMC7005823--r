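#' Broom-style tidiers for screen results
#'
#' `tidy()` returns the underlying per-probe (or per-image) table as a plain
#' tibble; `glance()` returns a one-row summary.
#'
#' @param x a `phenoprobe_ranking`, `phenoprobe_fold_change`,
#'   `phenoprobe_embedding` or `phenoprobe_analysis` object.
#' @param ... ignored.
#' @name tidiers
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidiers
#' @method tidy phenoprobe_ranking
#' @export
tidy.phenoprobe_ranking <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidiers
#' @method glance phenoprobe_ranking
#' @export
glance.phenoprobe_ranking <- function(x, ...) {
  tibble::tibble(
    n_probes = nrow(x),
    top_probe = x$probe_sku[x$rank == 1][1],
    max_dunn = max(x$dunn_index),
    median_dunn = median(x$dunn_index),
    n_infinite = sum(is.infinite(x$dunn_index)))
}

#' @rdname tidiers
#' @method tidy phenoprobe_fold_change
#' @export
tidy.phenoprobe_fold_change <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidiers
#' @method glance phenoprobe_fold_change
#' @export
glance.phenoprobe_fold_change <- function(x, ...) {
  fin <- x$fold_change[is.finite(x$fold_change)]
  tibble::tibble(
    n_probes = nrow(x),
    top_probe = x$probe_sku[1],
    max_fold_change = if (length(fin)) max(fin) else NA_real_,
    median_fold_change = if (length(fin)) median(fin) else NA_real_)
}

#' @rdname tidiers
#' @method tidy phenoprobe_embedding
#' @export
tidy.phenoprobe_embedding <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidiers
#' @method glance phenoprobe_embedding
#' @export
glance.phenoprobe_embedding <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(n_points = nrow(x), perplexity = cfg$perplexity,
                 n_iter = cfg$n_iter, seed = cfg$seed)
}

#' @rdname tidiers
#' @method tidy phenoprobe_analysis
#' @export
tidy.phenoprobe_analysis <- function(x, ...) tidy(x$ranking)

#' @rdname tidiers
#' @method glance phenoprobe_analysis
#' @export
glance.phenoprobe_analysis <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(mode = x$mode,
                   n_images = nrow(x$features),
                   n_features = length(feature_columns(x$features)),
                   n_retained = length(feature_columns(x$reduced))),
    glance(x$ranking))
}

#' @export
print.phenoprobe_analysis <- function(x, ...) {
  cat(sprintf("Screen analysis (%s mode): %d images, %d -> %d features\n",
              x$mode, nrow(x$features),
              length(feature_columns(x$features)),
              length(feature_columns(x$reduced))))
  print(utils::head(tibble::as_tibble(x$ranking), 15))
  invisible(x)
}
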