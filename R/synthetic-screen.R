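#' Synthetic fluorescent-probe screens
#'
#' Renders complete two-channel (DNA + probe) synthetic screens with known
#' ground truth: which probes carry a real phenotype difference between the
#' KO and WT conditions, and how strong the effect is. Fields emulate the
#' phenotype classes seen in live-probe screens: diffuse cytoplasmic stain,
#' punctate accumulation, nuclear stain, and absent staining with optional
#' low-intensity speckle artifacts.
#'
#' @name synthetic-screen
NULL

#' Describe a probe staining phenotype
#'
#' @param stain_class one of `"diffuse"`, `"puncta"`, `"nuclear"`,
#'   `"no_stain"`.
#' @param base_intensity baseline stain level in \[0, 1\]; forced to 0 for
#'   `no_stain` (below the noise floor by construction).
#' @param puncta_count Poisson mean number of bright puncta per field
#'   (used only when `stain_class = "puncta"`).
#' @param puncta_radius_px punctum radius in pixels.
#' @param puncta_intensity punctum peak intensity in \[0, 1\].
#' @param artifact_rate Poisson mean number of dim speckle artifacts per
#'   field (used only when `stain_class = "no_stain"`).
#' @param autofluorescence faint cytoplasmic background level in \[0, 1\]
#'   for unstained cells (`no_stain` only); real unstained wells are not
#'   flat noise, they show weak cell-shaped autofluorescence.
#' @return a `phenotype_spec` list.
#' @export
phenotype_spec <- function(stain_class = c("diffuse", "puncta", "nuclear", "no_stain"),
                           base_intensity = 0.35,
                           puncta_count = 0,
                           puncta_radius_px = 2,
                           puncta_intensity = 0.9,
                           artifact_rate = 0,
                           autofluorescence = 0) {
  stain_class <- match.arg(stain_class)
  stopifnot(base_intensity >= 0, base_intensity <= 1,
            puncta_count >= 0, puncta_radius_px > 0,
            puncta_intensity >= 0, puncta_intensity <= 1,
            artifact_rate >= 0, autofluorescence >= 0, autofluorescence <= 1)
  if (stain_class == "no_stain") base_intensity <- 0
  if (stain_class != "no_stain") autofluorescence <- 0
  structure(list(stain_class = stain_class,
                 base_intensity = base_intensity,
                 puncta_count = puncta_count,
                 puncta_radius_px = puncta_radius_px,
                 puncta_intensity = puncta_intensity,
                 artifact_rate = artifact_rate,
                 autofluorescence = autofluorescence),
            class = "phenotype_spec")
}

# Soft (sigmoid-edged) disk mass centred at (cx, cy); dx/dy are coordinate
# matrices. Soft edges keep the render differentiable-looking under blur-free
# synthesis.
soft_disk <- function(d, radius, softness = 0.8) {
  1 / (1 + exp((d - radius) / softness))
}

place_centers <- function(n, size, min_sep, margin, max_tries = 2000L) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort(sprintf(
        "Could not place %d non-overlapping nuclei in a %d px field.", n, size),
        class = "phenoprobe_placement_error")
    }
    cand <- runif(2, margin, size - margin)
    if (placed > 0L) {
      d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
            (centers[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < min_sep^2) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  centers
}

#' Render one synthetic two-channel field
#'
#' Channel `dna` holds `cells` non-overlapping soft-edged nuclei; channel
#' `probe` holds the stain described by `phenotype`. Both channels carry
#' Poisson shot noise (photon scale `photon_scale`) plus additive Gaussian
#' read noise of standard deviation `noise_sigma`, and are clipped to
#' \[0, 1\].
#'
#' @param phenotype a [phenotype_spec()].
#' @param cells number of nuclei in the field.
#' @param size field edge length in pixels (>= 64).
#' @param seed integer RNG seed; the render is a pure function of its
#'   arguments.
#' @param nucleus_radius_px nucleus radius in pixels.
#' @param noise_sigma Gaussian read-noise standard deviation.
#' @param photon_scale Poisson photon-count scale (larger = less shot noise).
#' @return list with matrices `dna` and `probe` in \[0, 1\].
#' @examples
#' f <- render_field(phenotype_spec("puncta", puncta_count = 10), cells = 5,
#'                   size = 96, seed = 1)
#' range(f$probe)
#' @export
render_field <- function(phenotype, cells, size = 128L, seed = 0L,
                         nucleus_radius_px = 6, noise_sigma = 0.01,
                         photon_scale = 200) {
  stopifnot(inherits(phenotype, "phenotype_spec"))
  if (size < 64L) abort("Field size must be at least 64 px.")
  if (cells < 0L) abort("`cells` must be nonnegative.")
  with_seed(seed, {
    r <- nucleus_radius_px
    cyto_r <- 2.5 * r
    xs <- matrix(rep(seq_len(size), size), size)
    ys <- t(xs)
    centers <- place_centers(cells, size, min_sep = 2 * r + 3,
                             margin = r + 2)

    dna <- matrix(0, size, size)
    probe <- matrix(0, size, size)
    if (cells > 0L) {
      for (i in seq_len(cells)) {
        d <- sqrt((xs - centers[i, 1])^2 + (ys - centers[i, 2])^2)
        dna <- pmax(dna, 0.85 * soft_disk(d, r))
        cls <- phenotype$stain_class
        if (cls %in% c("diffuse", "puncta")) {
          # cytoplasmic annulus: inside cyto_r but attenuated over the nucleus
          annulus <- soft_disk(d, cyto_r, softness = 1.5) *
            (1 - 0.65 * soft_disk(d, r))
          probe <- pmax(probe, phenotype$base_intensity * annulus)
        } else if (cls == "nuclear") {
          probe <- pmax(probe, phenotype$base_intensity * soft_disk(d, r))
        } else if (cls == "no_stain" && phenotype$autofluorescence > 0) {
          annulus <- soft_disk(d, cyto_r, softness = 1.5) *
            (1 - 0.65 * soft_disk(d, r))
          probe <- pmax(probe, phenotype$autofluorescence * annulus)
        }
      }
      if (phenotype$stain_class == "puncta") {
        n_p <- rpois(1, phenotype$puncta_count)
        if (n_p > 0) {
          host <- sample.int(cells, n_p, replace = TRUE)
          rad <- runif(n_p, r * 0.7, cyto_r * 0.95)
          ang <- runif(n_p, 0, 2 * pi)
          px <- pmin(pmax(centers[host, 1] + rad * cos(ang), 2), size - 1)
          py <- pmin(pmax(centers[host, 2] + rad * sin(ang), 2), size - 1)
          for (i in seq_len(n_p)) {
            d <- sqrt((xs - px[i])^2 + (ys - py[i])^2)
            probe <- pmax(probe,
                          phenotype$puncta_intensity *
                            soft_disk(d, phenotype$puncta_radius_px,
                                      softness = 0.5))
          }
        }
      }
    }
    if (phenotype$stain_class == "no_stain" && phenotype$artifact_rate > 0) {
      n_a <- rpois(1, phenotype$artifact_rate)
      if (n_a > 0) {
        ax <- runif(n_a, 2, size - 1)
        ay <- runif(n_a, 2, size - 1)
        # barely over the noise ceiling: invisible to whole-image intensity
        # statistics, but spatially coherent (detectable at object level)
        a_int <- runif(n_a, 2.5, 4) * noise_sigma
        for (i in seq_len(n_a)) {
          d <- sqrt((xs - ax[i])^2 + (ys - ay[i])^2)
          probe <- pmin(probe + a_int[i] * soft_disk(d, 1.8, softness = 0.5), 1)
        }
      }
    }
    add_noise <- function(img) {
      shot <- matrix(rpois(length(img), img * photon_scale) / photon_scale,
                     nrow(img))
      read <- matrix(rnorm(length(img), 0, noise_sigma), nrow(img))
      pmin(pmax(shot + read, 0), 1)
    }
    list(dna = add_noise(dna), probe = add_noise(probe))
  })
}

#' Configure a synthetic screen
#'
#' The defaults reproduce the layout of the live-probe screen the package
#' models: a 44-probe panel, each probe imaged in 2 conditions x 2 technical
#' replicates x 3 fields = 12 images per treatment arm, with the 8
#' published-phenotype probes as true positives (KO-side punctate
#' accumulation) and one no-stain probe carrying low-intensity artifacts in
#' the KO arm only (an artifact confounder, not a true positive).
#'
#' @param n_probes number of probes (taken in panel order, <= 44).
#' @param probe_skus optional character vector of panel SKUs to screen
#'   (overrides `n_probes`).
#' @param n_true_positives number of probes given a real KO phenotype shift;
#'   defaults to the 8 published-phenotype probes when `n_probes` covers them.
#' @param effect_puncta_count Poisson mean of KO-side puncta added for true
#'   positives (the effect delta; WT side has none).
#' @param artifact_probe include the artifact-confounder no-stain probe.
#' @param artifact_rate_ko,artifact_rate_wt mean speckle artifacts per field
#'   for that probe in each condition.
#' @param image_size_px square field size (>= 64).
#' @param cells_per_image mean nuclei per field (Poisson, min 3).
#' @param nucleus_radius_px nucleus radius.
#' @param noise_sigma,photon_scale noise model, see [render_field()].
#' @param treatments character vector of treatment arms.
#' @param treatment_effect_multiplier named numeric multiplier applied to the
#'   KO-WT effect delta per treatment (e.g. `c(DMSO = 1, mTORi = 2)`),
#'   emulating a treatment that accentuates the phenotype.
#' @param seed master seed; per-image seeds are derived from it by a stable
#'   hash of the image key, so adding probes does not perturb existing images.
#' @return a `screen_config` list.
#' @export
screen_config <- function(n_probes = 44L,
                          probe_skus = NULL,
                          n_true_positives = NULL,
                          effect_puncta_count = 18,
                          artifact_probe = TRUE,
                          artifact_rate_ko = 10,
                          artifact_rate_wt = 0,
                          image_size_px = 128L,
                          cells_per_image = 12,
                          nucleus_radius_px = 6,
                          noise_sigma = 0.01,
                          photon_scale = 200,
                          treatments = "DMSO",
                          treatment_effect_multiplier = NULL,
                          seed = 0L) {
  panel <- panel_manifest()
  if (!is.null(probe_skus)) {
    missing <- setdiff(probe_skus, panel$sku)
    if (length(missing)) {
      abort(sprintf("Unknown probe SKU(s): %s.", paste(missing, collapse = ", ")))
    }
    panel <- panel[match(probe_skus, panel$sku), ]
    n_probes <- nrow(panel)
  } else {
    if (n_probes > nrow(panel)) {
      abort(sprintf("n_probes must be <= the panel size (%d).", nrow(panel)))
    }
    panel <- panel[seq_len(n_probes), ]
  }
  if (image_size_px < 64L) abort("image_size_px must be >= 64.")
  published <- c("N1148", "D3922", "H34475", "D3921", "D3821", "D3822",
                 "N3786", "V12390")
  if (is.null(n_true_positives)) {
    tp <- intersect(published, panel$sku)
  } else {
    if (n_true_positives > n_probes) {
      abort("n_true_positives must be <= n_probes.")
    }
    tp <- intersect(published, panel$sku)
    if (length(tp) >= n_true_positives) {
      tp <- tp[seq_len(n_true_positives)]
    } else {
      extra <- setdiff(panel$sku, tp)
      tp <- c(tp, extra[seq_len(n_true_positives - length(tp))])
    }
  }
  if (is.null(treatment_effect_multiplier)) {
    treatment_effect_multiplier <- stats::setNames(
      ifelse(treatments == "DMSO", 1, 2), treatments)
  }
  if (any(treatment_effect_multiplier < 0)) {
    abort("treatment_effect_multiplier must be >= 0.")
  }
  artifact_sku <- if (artifact_probe && "Q2005" %in% panel$sku) "Q2005" else NA_character_
  structure(list(
    panel = panel, true_positives = tp,
    effect_puncta_count = effect_puncta_count,
    artifact_sku = artifact_sku,
    artifact_rate_ko = artifact_rate_ko, artifact_rate_wt = artifact_rate_wt,
    image_size_px = as.integer(image_size_px),
    cells_per_image = cells_per_image,
    nucleus_radius_px = nucleus_radius_px,
    noise_sigma = noise_sigma, photon_scale = photon_scale,
    treatments = treatments,
    treatment_effect_multiplier = treatment_effect_multiplier,
    seed = as.integer(seed)), class = "screen_config")
}

# Deterministic baseline phenotype for a probe slot: lipid probes diffuse at
# varying intensity, organelle/drug probes punctate (same in both
# conditions), ion/stress probes nuclear or dim diffuse.
baseline_phenotype <- function(sku, category, idx) {
  lvl <- 0.25 + 0.02 * (idx %% 6)
  if (grepl("^Lipid", category)) {
    phenotype_spec("diffuse", base_intensity = lvl)
  } else if (category %in% c("Organelle morphology", "Drug conjugate")) {
    phenotype_spec("puncta", base_intensity = lvl * 0.6,
                   puncta_count = 6 + idx %% 4, puncta_radius_px = 1.8,
                   puncta_intensity = 0.7)
  } else if (category == "Cellular stress") {
    phenotype_spec("nuclear", base_intensity = lvl)
  } else {
    phenotype_spec("diffuse", base_intensity = lvl * 0.8)
  }
}

#' Ground-truth phenotype specs for a configured screen
#'
#' @param config a [screen_config()].
#' @return tibble with one row per (probe, condition, treatment) and a
#'   list-column `spec` of [phenotype_spec()] objects, plus `is_true_positive`
#'   and the numeric `effect_delta` (KO-side puncta-count delta).
#' @export
screen_truth <- function(config) {
  grid <- tidyr::expand_grid(
    idx = seq_len(nrow(config$panel)),
    treatment = config$treatments,
    condition = CONDITIONS)
  grid$probe_sku <- config$panel$sku[grid$idx]
  grid$category <- config$panel$category[grid$idx]
  grid$is_true_positive <- grid$probe_sku %in% config$true_positives
  mult <- config$treatment_effect_multiplier[grid$treatment]
  grid$effect_delta <- ifelse(grid$is_true_positive,
                              config$effect_puncta_count * mult, 0)
  grid$spec <- purrr::pmap(
    list(grid$probe_sku, grid$category, grid$idx, grid$condition,
         grid$effect_delta),
    function(sku, cat, idx, cond, delta) {
      if (!is.na(config$artifact_sku) && sku == config$artifact_sku) {
        rate <- if (cond == "KO") config$artifact_rate_ko else config$artifact_rate_wt
        return(phenotype_spec("no_stain", artifact_rate = rate,
                              autofluorescence = 0.05))
      }
      base <- baseline_phenotype(sku, cat, idx)
      if (cond == "KO" && delta > 0) {
        # true positive: KO side gains puncta on top of the baseline stain
        phenotype_spec("puncta", base_intensity = base$base_intensity,
                       puncta_count = (if (base$stain_class == "puncta")
                         base$puncta_count else 0) + delta,
                       puncta_radius_px = 2, puncta_intensity = 0.9)
      } else base
    })
  tibble::as_tibble(grid[c("probe_sku", "category", "condition", "treatment",
                           "is_true_positive", "effect_delta", "spec")])
}

#' Generate a complete synthetic screen
#'
#' Renders 2 conditions x 2 replicates x 3 fields = 12 images per probe per
#' treatment arm, writes each channel as a 16-bit grayscale TIFF
#' (`<image_id>_dna.tif`, `<image_id>_probe.tif`), and writes the plate map
#' (`plate_map.csv`) and ground truth (`ground_truth.csv`) alongside. Output
#' is a pure function of the configuration, including its seed.
#'
#' @param config a [screen_config()].
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @param write_images set `FALSE` to produce the layout/truth tables and
#'   in-memory images only (no files); images are then returned in the
#'   `images` list-column of the layout.
#' @return a list with `layout` (validated plate map tibble; with an
#'   `images` list-column when `write_images = FALSE`), `truth`
#'   (per-probe ground truth), and `dir`.
#' @export
generate_screen <- function(config = screen_config(), out_dir = NULL,
                            overwrite = FALSE, write_images = !is.null(out_dir)) {
  if (write_images) {
    if (is.null(out_dir)) abort("`out_dir` is required when writing images.")
    if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite) {
      abort(sprintf("Output directory '%s' is not empty; set overwrite = TRUE.",
                    out_dir))
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  truth <- screen_truth(config)
  grid <- tidyr::expand_grid(
    probe_sku = config$panel$sku,
    treatment = config$treatments,
    condition = CONDITIONS,
    replicate = 1:2,
    field = 1:3)
  grid$image_id <- sprintf("%s_%s_%s_r%d_f%d", grid$probe_sku, grid$condition,
                           gsub("[^A-Za-z0-9]", "", grid$treatment),
                           grid$replicate, grid$field)
  grid$path <- if (write_images) {
    file.path(out_dir, paste0(grid$image_id, "_probe.tif"))
  } else NA_character_

  spec_key <- paste(truth$probe_sku, truth$condition, truth$treatment)
  specs <- stats::setNames(truth$spec, spec_key)

  # densest packing the rejection sampler can reliably satisfy
  r <- config$nucleus_radius_px
  cell_cap <- max(3L, floor(0.55 * ((config$image_size_px - 2 * (r + 2)) /
                                      (2 * r + 3))^2))
  render_one <- function(sku, cond, treat, rep, fld) {
    seed_i <- derive_seed(config$seed, sku, cond, treat, rep, fld)
    n_cells <- min(cell_cap,
                   max(3L, with_seed(seed_i + 1L,
                                     rpois(1, config$cells_per_image))))
    render_field(specs[[paste(sku, cond, treat)]], cells = n_cells,
                 size = config$image_size_px, seed = seed_i,
                 nucleus_radius_px = config$nucleus_radius_px,
                 noise_sigma = config$noise_sigma,
                 photon_scale = config$photon_scale)
  }
  images <- purrr::pmap(
    list(grid$probe_sku, grid$condition, grid$treatment, grid$replicate,
         grid$field),
    function(sku, cond, treat, rep, fld) {
      img <- render_one(sku, cond, treat, rep, fld)
      if (write_images) {
        id <- sprintf("%s_%s_%s_r%d_f%d", sku, cond,
                      gsub("[^A-Za-z0-9]", "", treat), rep, fld)
        tiff::writeTIFF(img$dna, file.path(out_dir, paste0(id, "_dna.tif")),
                        bits.per.sample = 16L, compression = "none")
        tiff::writeTIFF(img$probe, file.path(out_dir, paste0(id, "_probe.tif")),
                        bits.per.sample = 16L, compression = "none")
        NULL
      } else img
    })

  layout <- grid[c("image_id", "probe_sku", "condition", "treatment",
                   "replicate", "field", "path")]
  layout <- validate_layout(layout)
  truth_table <- truth |>
    dplyr::distinct(.data$probe_sku, .data$is_true_positive) |>
    dplyr::left_join(
      truth |> dplyr::filter(.data$condition == "KO") |>
        dplyr::group_by(.data$probe_sku) |>
        dplyr::summarise(effect_delta = max(.data$effect_delta)),
      by = "probe_sku")
  if (write_images) {
    write_plate_map(layout, file.path(out_dir, "plate_map.csv"))
    readr::write_csv(truth_table, file.path(out_dir, "ground_truth.csv"))
  } else {
    layout$image <- images
  }
  list(layout = layout, truth = truth_table, dir = out_dir)
}

#' Read the two channels of a screen image
#'
#' @param probe_path path of the probe-channel TIFF (the `path` column of a
#'   layout); the DNA channel is found by the `_probe.tif` -> `_dna.tif`
#'   naming convention.
#' @return list with matrices `dna` and `probe`.
#' @export
read_field <- function(probe_path) {
  dna_path <- sub("_probe\\.tif$", "_dna.tif", probe_path)
  list(dna = unclass(tiff::readTIFF(dna_path)),
       probe = unclass(tiff::readTIFF(probe_path)))
}
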