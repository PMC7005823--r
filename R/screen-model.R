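#' Screen layouts, probe panels and result tables
#'
#' A screen layout is the plate map of an imaging screen: one row per acquired
#' field, mapping an image to its probe, condition (KO/WT), treatment arm,
#' technical replicate and field index, plus the path of the probe-channel
#' TIFF on disk. These tables are the shared vocabulary of every other
#' function in the package.
#'
#' @name screen-model
NULL

PLATE_MAP_COLUMNS <- c("image_id", "probe_sku", "condition", "treatment",
                       "replicate", "field", "path")
CONDITIONS <- c("KO", "WT")

#' Validate a screen layout table
#'
#' Checks the plate-map invariants: required columns present, image ids
#' unique, conditions in `KO`/`WT`, the (probe, condition, treatment,
#' replicate, field) key unique, and (unless `strict = FALSE`) every
#' (probe, treatment) arm covered by exactly the two conditions.
#'
#' @param layout a data frame with the plate-map columns.
#' @param strict error (rather than warn) when a (probe, treatment) arm does
#'   not span both conditions.
#' @return the validated layout as a tibble, invisibly classed
#'   `"phenoprobe_layout"`.
#' @export
validate_layout <- function(layout, strict = TRUE) {
  missing <- setdiff(PLATE_MAP_COLUMNS, names(layout))
  if (length(missing)) {
    abort(sprintf("Plate map is missing required column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "phenoprobe_schema_error")
  }
  layout <- tibble::as_tibble(layout)
  layout$replicate <- as.integer(layout$replicate)
  layout$field <- as.integer(layout$field)

  dup_id <- unique(layout$image_id[duplicated(layout$image_id)])
  if (length(dup_id)) {
    abort(sprintf("Duplicate image_id value(s): %s.",
                  paste(dup_id, collapse = ", ")),
          class = "phenoprobe_validation_error")
  }
  bad_cond <- setdiff(unique(layout$condition), CONDITIONS)
  if (length(bad_cond)) {
    abort(sprintf("condition must be one of %s; found: %s.",
                  paste(CONDITIONS, collapse = ", "),
                  paste(bad_cond, collapse = ", ")),
          class = "phenoprobe_validation_error")
  }
  if (any(layout$replicate < 1L) || any(layout$field < 1L)) {
    abort("replicate and field must be positive integers.",
          class = "phenoprobe_validation_error")
  }
  key <- paste(layout$probe_sku, layout$condition, layout$treatment,
               layout$replicate, layout$field, sep = "/")
  if (anyDuplicated(key)) {
    abort(sprintf("Duplicate (probe, condition, treatment, replicate, field) key(s): %s.",
                  paste(unique(key[duplicated(key)]), collapse = "; ")),
          class = "phenoprobe_validation_error")
  }

  arm_cover <- layout |>
    dplyr::distinct(.data$probe_sku, .data$treatment, .data$condition) |>
    dplyr::count(.data$probe_sku, .data$treatment, name = "n_cond") |>
    dplyr::filter(.data$n_cond != 2L)
  if (nrow(arm_cover)) {
    msg <- sprintf(
      "Probe/treatment arm(s) not covered by both conditions: %s.",
      paste(sprintf("%s (%s)", arm_cover$probe_sku, arm_cover$treatment),
            collapse = ", "))
    if (strict) abort(msg, class = "phenoprobe_validation_error") else warn(msg)
  }
  class(layout) <- c("phenoprobe_layout", class(layout))
  layout
}

#' Read and validate a plate map
#'
#' @param path CSV file with columns `image_id`, `probe_sku`, `condition`,
#'   `treatment`, `replicate`, `field`, `path`.
#' @param strict see [validate_layout()].
#' @return a validated layout tibble.
#' @examples
#' map <- tibble::tibble(
#'   image_id = c("a", "b"), probe_sku = "D3922",
#'   condition = c("KO", "WT"), treatment = "DMSO",
#'   replicate = 1L, field = 1L, path = c("a.tif", "b.tif"))
#' f <- tempfile(fileext = ".csv")
#' readr::write_csv(map, f)
#' load_plate_map(f)
#' @export
load_plate_map <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    abort(sprintf("Plate map file not found: %s", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_layout(raw, strict = strict)
}

#' Write a plate map
#'
#' Inverse of [load_plate_map()]; round-trips all fields losslessly.
#' @param layout a layout tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_map <- function(layout, path) {
  readr::write_csv(layout[PLATE_MAP_COLUMNS], path)
  invisible(path)
}

#' The bundled fluorescent-probe panel
#'
#' Returns the default 44-probe panel: for each probe its catalogue SKU, a
#' short name, the readout category and the application (what the probe
#' stains). The eight probes with published identities are verbatim; the
#' remaining entries are representative placeholders spread over the panel's
#' readout categories (lipid probes deliberately over-represented, matching
#' the panel's emphasis on lipid metabolism and trafficking).
#'
#' @return a tibble with columns `sku`, `name`, `category`, `application`.
#' @examples
#' nrow(panel_manifest())
#' probe_info("D3922")
#' @export
panel_manifest <- function() {
  path <- system.file("extdata", "probe_panel.csv", package = "phenoprobe",
                      mustWork = TRUE)
  cache_get_or("panel_manifest", function() {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = "cccc")
  })
}

#' @rdname panel_manifest
#' @param sku a probe SKU present in the panel.
#' @export
probe_info <- function(sku) {
  panel <- panel_manifest()
  hit <- panel[panel$sku == sku, ]
  if (!nrow(hit)) {
    abort(sprintf("Probe SKU '%s' not found in the panel.", sku),
          class = "phenoprobe_not_found_error")
  }
  hit
}

#' Write / read a probe ranking table
#'
#' Rankings are CSV with a stable column order; an infinite Dunn index
#' (degenerate single-point clusters) is serialised as the literal token
#' `"inf"` and restored on read.
#'
#' @param ranking a probe ranking tibble (see [rank_probes()]).
#' @param path CSV path.
#' @return `path` invisibly (write); the ranking tibble (read).
#' @export
write_ranking <- function(ranking, path) {
  if (!nrow(ranking)) abort("Refusing to write an empty ranking.")
  out <- as.data.frame(ranking)
  num_cols <- intersect(c("dunn_index", "fold_change"), names(out))
  for (col in num_cols) {
    out[[col]] <- ifelse(is.infinite(out[[col]]), "inf",
                         format(out[[col]], digits = 17, trim = TRUE,
                                scientific = FALSE))
  }
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE),
    error = function(e) abort(sprintf("Cannot write ranking to '%s': %s",
                                      path, conditionMessage(e))))
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in intersect(c("dunn_index", "fold_change"), names(raw))) {
    v <- as.character(raw[[col]])
    raw[[col]] <- ifelse(v == "inf", Inf, suppressWarnings(as.numeric(v)))
  }
  if ("rank" %in% names(raw)) raw$rank <- as.integer(raw$rank)
  class(raw) <- c("phenoprobe_ranking", class(raw))
  raw
}
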