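#' t-SNE embedding of a reduced feature matrix
#'
#' Embeds all images of a screen into 2D with exact t-SNE. Features are
#' z-scored before embedding; zero-variance columns are dropped. The
#' embedding is deterministic for identical input and seed (PCA
#' initialisation with sign-fixed loadings; the seed only enters if the
#' initialisation is degenerate). The perplexity is clipped to
#' `(n_points - 1) / 3`.
#'
#' @param reduced a reduced feature tibble with an `image_id` column (see
#'   [reduce_features()]); rows with any `NA` feature (flagged empty images
#'   from the segmentation path) are dropped with a message.
#' @param perplexity t-SNE perplexity (default 30).
#' @param seed integer seed, recorded in provenance.
#' @param n_iter gradient-descent iterations.
#' @return tibble `image_id`, `x`, `y`, classed `phenoprobe_embedding`,
#'   with an attribute `config` recording perplexity/seed/iterations.
#' @export
embed_tsne <- function(reduced, perplexity = 30, seed = 0L, n_iter = 750L) {
  cols <- feature_columns(reduced)
  X <- as.matrix(reduced[cols])
  storage.mode(X) <- "double"
  keep_row <- stats::complete.cases(X)
  if (!all(keep_row)) {
    inform(sprintf("Dropping %d image(s) with missing features (empty images).",
                   sum(!keep_row)))
    X <- X[keep_row, , drop = FALSE]
  }
  ids <- reduced$image_id[keep_row]
  n <- nrow(X)
  if (n < 5) abort("t-SNE embedding needs at least 5 images.")
  perplexity <- min(perplexity, (n - 1) / 3)
  if (perplexity >= n) abort("perplexity must be below the number of points.")
  sds <- apply(X, 2, sd)
  X <- X[, sds > 0, drop = FALSE]
  if (!ncol(X)) abort("No non-constant features to embed.")
  X <- scale(X)
  # identical feature rows must embed identically: run t-SNE on unique rows
  # and share coordinates (coincident twins would otherwise drift apart
  # through floating-point asymmetry in the gradient sums)
  key <- apply(X, 1, paste, collapse = "\r")
  idx <- match(key, key)
  uniq <- !duplicated(key)
  perp_u <- min(perplexity, (sum(uniq) - 1) / 3)
  Yu <- tsne_exact(X[uniq, , drop = FALSE], perplexity = perp_u,
                   n_iter = n_iter, seed = seed)
  Y <- Yu[match(idx, which(uniq)), , drop = FALSE]
  out <- tibble::tibble(image_id = ids, x = Y[, 1], y = Y[, 2])
  attr(out, "config") <- list(perplexity = perplexity, seed = seed,
                              n_iter = n_iter, n_points = n)
  class(out) <- unique(c("phenoprobe_embedding", class(out)))
  out
}

#' Dunn index of two point sets
#'
#' Cluster-separation statistic for two clusters: the minimum inter-cluster
#' distance (single linkage across the two sets) divided by the largest
#' within-cluster diameter (complete diameter of either set). Degenerate
#' cases: zero separation gives 0; zero diameters with positive separation
#' give `Inf`.
#'
#' @param points_a,points_b numeric matrices (or data frames) with 2 columns
#'   of coordinates; each must be nonempty.
#' @return a nonnegative number, possibly `Inf`.
#' @examples
#' dunn_index(rbind(c(0, 0), c(0, 1)), rbind(c(10, 0), c(10, 1)))  # 10
#' @export
dunn_index <- function(points_a, points_b) {
  a <- as.matrix(points_a); b <- as.matrix(points_b)
  if (!nrow(a) || !nrow(b)) abort("Both point sets must be nonempty.")
  cross <- cross_min_dist(a, b)
  if (cross == 0) return(0)
  diam <- max(set_diameter(a), set_diameter(b))
  if (diam == 0) return(Inf)
  cross / diam
}

cross_min_dist <- function(a, b) {
  # coordinate-difference form: numerically identical to computing each
  # pairwise distance directly (the expanded inner-product form loses
  # precision for near-coincident points)
  d2 <- 0
  for (j in seq_len(ncol(a))) {
    d2 <- d2 + outer(a[, j], b[, j], "-")^2
  }
  sqrt(min(d2))
}

set_diameter <- function(a) {
  if (nrow(a) < 2) return(0)
  max(stats::dist(a))
}

#' Rank probes by KO-vs-WT separation
#'
#' For every probe in one treatment arm, the Dunn index between its KO and
#' WT image coordinates is computed on the single global embedding of the
#' whole screen, and probes are ranked by descending Dunn index (ties broken
#' by ascending SKU). A probe missing either condition is excluded with a
#' warning.
#'
#' @param embedding a [embed_tsne()] result (or any tibble with `image_id`,
#'   `x`, `y`).
#' @param layout the screen layout.
#' @param treatment the treatment arm to rank (default `"DMSO"`).
#' @return tibble `probe_sku`, `probe_name`, `category`, `dunn_index`,
#'   `rank`, classed `phenoprobe_ranking`.
#' @export
rank_probes <- function(embedding, layout, treatment = "DMSO") {
  pts <- dplyr::inner_join(tibble::as_tibble(embedding)[c("image_id", "x", "y")],
                           tibble::as_tibble(layout),
                           by = "image_id") |>
    dplyr::filter(.data$treatment == !!treatment)
  if (!nrow(pts)) abort(sprintf("No images in treatment arm '%s'.", treatment))
  per_probe <- split(pts, pts$probe_sku)
  rows <- purrr::imap(per_probe, function(d, sku) {
    ko <- as.matrix(d[d$condition == "KO", c("x", "y")])
    wt <- as.matrix(d[d$condition == "WT", c("x", "y")])
    if (!nrow(ko) || !nrow(wt)) {
      warn(sprintf("Probe %s lacks a condition in arm '%s'; excluded.",
                   sku, treatment))
      return(NULL)
    }
    tibble::tibble(probe_sku = sku, dunn_index = dunn_index(ko, wt))
  })
  out <- dplyr::bind_rows(rows)
  panel <- panel_manifest()
  out <- dplyr::left_join(out, panel, by = c(probe_sku = "sku")) |>
    dplyr::rename(probe_name = "name") |>
    dplyr::select("probe_sku", "probe_name", "category", "dunn_index") |>
    dplyr::arrange(dplyr::desc(.data$dunn_index), .data$probe_sku) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- unique(c("phenoprobe_ranking", class(out)))
  out
}

#' Dunn-index fold change between two treatment arms
#'
#' Embeds both arms jointly (a single t-SNE over all rows, so Dunn indices
#' are measured in one common space), computes the per-probe Dunn index in
#' each arm, and reports `fold_change = dunn_treated / dunn_control`.
#' Sentinels: control 0 with treated positive gives `Inf`; both 0 give 1.
#'
#' @param reduced reduced feature tibble covering both arms.
#' @param layout the screen layout.
#' @param control,treated names of the two treatment arms.
#' @param top_n if given, restrict the fold-change table to the probes
#'   ranked in the top `top_n` of the control arm — the usual workflow, since
#'   Dunn ratios are only meaningful for probes with real baseline
#'   separation.
#' @param perplexity,seed,n_iter passed to [embed_tsne()].
#' @return tibble `probe_sku`, `probe_name`, `category`, `dunn_control`,
#'   `dunn_treated`, `fold_change`, sorted by descending fold change;
#'   attribute `embedding` carries the joint embedding.
#' @export
fold_change_ranking <- function(reduced, layout, control = "DMSO",
                                treated = "mTORi", top_n = NULL,
                                perplexity = 30, seed = 0L, n_iter = 750L) {
  emb <- embed_tsne(reduced, perplexity = perplexity, seed = seed,
                    n_iter = n_iter)
  rc <- rank_probes(emb, layout, treatment = control)
  rt <- rank_probes(emb, layout, treatment = treated)
  missing <- setdiff(unique(layout$probe_sku),
                     intersect(rc$probe_sku, rt$probe_sku))
  if (length(missing)) {
    warn(sprintf("Probe(s) absent from an arm, excluded: %s.",
                 paste(missing, collapse = ", ")))
  }
  if (!is.null(top_n)) rc <- rc[rc$rank <= top_n, ]
  both <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(rc), "probe_sku", "probe_name",
                  "category", dunn_control = "dunn_index"),
    dplyr::select(tibble::as_tibble(rt), "probe_sku",
                  dunn_treated = "dunn_index"),
    by = "probe_sku")
  both$fold_change <- dplyr::case_when(
    both$dunn_control == 0 & both$dunn_treated == 0 ~ 1,
    both$dunn_control == 0 ~ Inf,
    is.infinite(both$dunn_treated) & is.infinite(both$dunn_control) ~ 1,
    TRUE ~ both$dunn_treated / both$dunn_control)
  out <- dplyr::arrange(both, dplyr::desc(.data$fold_change), .data$probe_sku)
  attr(out, "embedding") <- emb
  class(out) <- unique(c("phenoprobe_fold_change", class(out)))
  out
}

#' End-to-end screen analysis
#'
#' Convenience wrapper: extract features for every image of a layout, reduce
#' them, embed, and rank the probes of one treatment arm.
#'
#' @param layout validated screen layout (with TIFFs on disk, or in-memory
#'   images from `generate_screen(write_images = FALSE)`).
#' @param mode `"charm"` (whole-image, default) or `"segmentation"`.
#' @param treatment treatment arm to rank.
#' @param config a [reduction_config()].
#' @param perplexity,seed passed to [embed_tsne()].
#' @return list with `features`, `reduced`, `embedding`, `ranking`, classed
#'   `phenoprobe_analysis`.
#' @export
profile_screen <- function(layout, mode = c("charm", "segmentation"),
                           treatment = "DMSO", config = reduction_config(),
                           perplexity = 30, seed = 0L) {
  mode <- match.arg(mode)
  features <- extract_features(layout, mode = mode)
  reduced <- reduce_features(features, config)
  embedding <- embed_tsne(reduced, perplexity = perplexity, seed = seed)
  ranking <- rank_probes(embedding, layout, treatment = treatment)
  structure(list(features = features, reduced = reduced,
                 embedding = embedding, ranking = ranking, mode = mode),
            class = "phenoprobe_analysis")
}
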