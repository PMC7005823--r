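#' The 923-feature whole-image manifest
#'
#' The feature bank is a fixed (transform path x family) grid totalling
#' exactly 923 named features. The statistical families (pixel statistics,
#' multiscale histograms, direction-averaged Haralick texture, Tamura
#' texture, image moments) run on all seven transform planes; the remaining
#' families run on the subsets listed below. The manifest is the single
#' source of truth for feature order and is identical on every platform.
#'
#' Grid: 5 stat families (12 + 24 + 26 + 6 + 16 = 84) x 7 planes = 588;
#' radon (12) x 4; chebyshev histogram (32) x 3; chebyshev-fourier (32) x 2;
#' zernike (25) x 3; gabor (14), edge statistics (28) and otsu object
#' statistics (10) on the raw plane: 588 + 48 + 96 + 64 + 75 + 14 + 28 +
#' 10 = 923.
#'
#' @return tibble with columns `feature_name`, `family`, `transform_path`,
#'   923 rows in extraction order.
#' @examples
#' nrow(charm_manifest())
#' @export
charm_manifest <- function() {
  cache_get_or("charm_manifest", build_charm_manifest)
}

STAT_PATHS <- c("raw", "fourier", "wavelet_approx", "wavelet_detail",
                "chebyshev", "edge", "wavelet_fourier")

CHARM_GRID <- list(
  pixel_stats = STAT_PATHS,
  multiscale_histograms = STAT_PATHS,
  haralick = STAT_PATHS,
  tamura = STAT_PATHS,
  moments_comb = STAT_PATHS,
  radon_stats = c("raw", "fourier", "wavelet_approx", "chebyshev"),
  chebyshev_stats = c("raw", "fourier", "edge"),
  chebyshev_fourier = c("raw", "wavelet_approx"),
  zernike = c("raw", "edge", "fourier"),
  gabor = "raw",
  edge_stats = "raw",
  otsu_object_stats = "raw")

family_feature_names <- function(family) {
  # canonical sub-names come from running the family on a tiny fixed plane
  key <- sprintf("famnames_%s", family)
  cache_get_or(key, function() {
    probe <- matrix(seq(0, 1, length.out = 64 * 64), 64)
    names(extract_family(probe, family))
  })
}

build_charm_manifest <- function() {
  rows <- purrr::imap(CHARM_GRID, function(paths, family) {
    sub <- family_feature_names(family)
    tidyr::expand_grid(transform_path = paths, sub = sub) |>
      dplyr::mutate(family = family,
                    feature_name = sprintf("%s__%s_%s", .data$transform_path,
                                           family, .data$sub))
  })
  out <- dplyr::bind_rows(rows)[c("feature_name", "family", "transform_path")]
  stopifnot(nrow(out) == 923L, !anyDuplicated(out$feature_name))
  tibble::as_tibble(out)
}

#' Export a feature manifest as CSV
#'
#' @param manifest a manifest tibble ([charm_manifest()] or
#'   [segmentation_manifest()]).
#' @param path output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path)
  invisible(path)
}

#' Segmentation-free whole-image feature extraction
#'
#' Computes the full 923-feature bank on one probe-channel image: the
#' transform stack is built once, then every (plane, family) cell of the
#' manifest grid is extracted. The result is a pure, deterministic function
#' of the pixel data. Non-finite values arising from degenerate statistics
#' are imputed as 0 (a message reports the count).
#'
#' @param image numeric matrix in \[0, 1\], at least 64 x 64.
#' @param quiet suppress the imputation message.
#' @return named numeric vector of length 923 in manifest order.
#' @examples
#' v <- extract_charm(matrix(runif(64 * 64), 64))
#' length(v)
#' @export
extract_charm <- function(image, quiet = FALSE) {
  assert_image(image, min_side = 64L)
  planes <- transform_stack(image)
  man <- charm_manifest()
  vals <- numeric(0)
  for (family in names(CHARM_GRID)) {
    for (path in CHARM_GRID[[family]]) {
      raw_v <- switch(family,
        pixel_stats = family_pixel_stats(planes[[path]]),
        multiscale_histograms = family_multiscale_histograms(planes[[path]]),
        haralick = family_haralick(planes[[path]]),
        tamura = family_tamura(planes[[path]]),
        moments_comb = family_moments_comb(planes[[path]]),
        radon_stats = family_radon_stats(planes[[path]]),
        chebyshev_stats = family_chebyshev_stats(planes[[path]]),
        chebyshev_fourier = family_chebyshev_fourier(planes[[path]]),
        zernike = family_zernike(planes[[path]]),
        gabor = family_gabor(planes[[path]]),
        edge_stats = family_edge_stats(planes[[path]]),
        otsu_object_stats = family_otsu_object_stats(planes[[path]]))
      vals <- c(vals, raw_v)
    }
  }
  n_bad <- sum(!is.finite(vals))
  if (n_bad > 0) {
    vals <- finite_or0(vals)
    if (!quiet) inform(sprintf("Imputed %d non-finite feature value(s) as 0.",
                               n_bad))
  }
  stats::setNames(vals, man$feature_name)
}

#' Extract a feature matrix for a whole screen
#'
#' Runs [extract_charm()] (mode `"charm"`) or the segmentation comparator
#' ([extract_segmentation()], mode `"segmentation"`) over every image of a
#' layout and assembles the images x features matrix.
#'
#' @param layout a validated layout tibble; its `path` column locates the
#'   probe-channel TIFFs (or, for in-memory screens from
#'   `generate_screen(write_images = FALSE)`, an `image` list-column holds
#'   the rendered channels).
#' @param mode `"charm"` or `"segmentation"`.
#' @param quiet suppress per-image messages.
#' @return tibble: `image_id` followed by the feature columns (923 for
#'   charm; 237 plus `n_objects` for segmentation, where empty images have
#'   NA features).
#' @export
extract_features <- function(layout, mode = c("charm", "segmentation"),
                             quiet = TRUE) {
  mode <- match.arg(mode)
  has_images <- "image" %in% names(layout)
  get_field <- function(i) {
    if (has_images) layout$image[[i]] else read_field(layout$path[i])
  }
  rows <- purrr::map(seq_len(nrow(layout)), function(i) {
    field <- get_field(i)
    if (mode == "charm") {
      as.list(extract_charm(field$probe, quiet = quiet))
    } else {
      as.list(extract_segmentation(field$dna, field$probe))
    }
  })
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble_row))
  dplyr::bind_cols(tibble::tibble(image_id = layout$image_id), out)
}
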