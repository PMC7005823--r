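test_that("rendered fields honour the phenotype spec", {
  sigma <- 0.01
  blank <- render_field(phenotype_spec("no_stain"), cells = 5, size = 96,
                        seed = 3, noise_sigma = sigma)
  # pure Poisson-Gaussian noise floor: the max of ~9k clipped Gaussian draws
  # sits a little above 4 sigma, far below any stain level
  expect_lt(max(blank$probe), 5.5 * sigma)
  expect_gt(max(blank$dna), 0.5)  # nuclei present regardless of stain

  empty <- render_field(phenotype_spec("diffuse"), cells = 0, size = 64,
                        seed = 1)
  expect_lt(max(empty$dna), 0.1)
  expect_equal(dim(empty$dna), c(64L, 64L))

  # puncta raise probe-channel variance over a diffuse stain
  pv <- sapply(1:6, function(s) {
    d <- render_field(phenotype_spec("diffuse", base_intensity = 0.35),
                      cells = 8, size = 96, seed = s)
    p <- render_field(phenotype_spec("puncta", base_intensity = 0.35,
                                     puncta_count = 20),
                      cells = 8, size = 96, seed = s)
    var(as.vector(p$probe)) - var(as.vector(d$probe))
  })
  expect_true(all(pv > 0))

  expect_error(render_field(phenotype_spec("diffuse"), cells = 5, size = 32),
               "64")
  expect_error(render_field(phenotype_spec("diffuse"), cells = 500,
                            size = 64),
               class = "phenoprobe_placement_error")
})

test_that("generated screens have 12 images per probe per treatment and are deterministic", {
  cfg <- screen_config(n_probes = 2, image_size_px = 64, seed = 7)
  scr <- generate_screen(cfg, write_images = FALSE)
  counts <- table(scr$layout$probe_sku)
  expect_true(all(counts == 12))
  expect_equal(nrow(scr$layout), 24L)

  # two treatments double the count
  cfg2 <- screen_config(n_probes = 2, image_size_px = 64,
                        treatments = c("DMSO", "mTORi"), seed = 7)
  scr2 <- generate_screen(cfg2, write_images = FALSE)
  expect_equal(nrow(scr2$layout), 48L)
  expect_true(all(table(scr2$layout$probe_sku, scr2$layout$treatment) == 12))

  # determinism: identical pixel data from identical config
  again <- generate_screen(cfg, write_images = FALSE)
  expect_identical(scr$layout$image, again$layout$image)

  # adding probes does not perturb existing images (per-image hashed seeds)
  cfg3 <- screen_config(n_probes = 3, image_size_px = 64, seed = 7)
  scr3 <- generate_screen(cfg3, write_images = FALSE)
  shared <- match(scr$layout$image_id, scr3$layout$image_id)
  expect_identical(scr$layout$image, scr3$layout$image[shared])
})

test_that("screens written to disk round-trip as 16-bit TIFF pairs", {
  cfg <- screen_config(n_probes = 1, artifact_probe = FALSE,
                       image_size_px = 64, seed = 2)
  dir <- withr::local_tempdir()
  scr <- generate_screen(cfg, out_dir = dir)
  expect_equal(length(list.files(dir, pattern = "\\.tif$")), 24L)  # 12 x 2 ch
  expect_true(file.exists(file.path(dir, "plate_map.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  layout <- load_plate_map(file.path(dir, "plate_map.csv"))
  field <- read_field(layout$path[1])
  expect_equal(dim(field$probe), c(64L, 64L))
  expect_true(all(field$probe >= 0 & field$probe <= 1))
  # refuses to clobber
  expect_error(generate_screen(cfg, out_dir = dir), "overwrite")
  # in-memory and on-disk pixel data agree to 16-bit quantisation
  mem <- generate_screen(cfg, write_images = FALSE)
  i <- match(layout$image_id[1], mem$layout$image_id)
  expect_lt(max(abs(field$probe - mem$layout$image[[i]]$probe)), 1 / 65535)
})

test_that("ground truth marks effects only where specs differ and encodes them monotonically", {
  cfg <- screen_config(n_probes = 14, seed = 5)  # includes the artifact probe
  truth <- screen_truth(cfg)
  # non-true-positive probes: identical KO and WT phenotype specs
  specs_equal <- truth |>
    dplyr::filter(!.data$is_true_positive) |>
    dplyr::group_by(.data$probe_sku, .data$treatment) |>
    dplyr::summarise(same = identical(.data$spec[[1]], .data$spec[[2]]),
                     .groups = "drop")
  expect_identical(cfg$artifact_sku, "Q2005")
  expect_true(all(specs_equal$same[!specs_equal$probe_sku %in% cfg$artifact_sku]))
  # ...except the artifact confounder, which differs only in artifact rate
  expect_false(all(specs_equal$same[specs_equal$probe_sku == cfg$artifact_sku]))

  # larger puncta delta -> larger KO-WT probe-channel variance gap
  gap <- function(delta) {
    mean(sapply(1:20, function(s) {
      ko <- render_field(phenotype_spec("puncta", base_intensity = 0.3,
                                        puncta_count = delta),
                         cells = 8, size = 64, seed = s)
      wt <- render_field(phenotype_spec("diffuse", base_intensity = 0.3),
                         cells = 8, size = 64, seed = s + 1000)
      var(as.vector(ko$probe)) - var(as.vector(wt$probe))
    }))
  }
  gaps <- sapply(c(3, 10, 25), gap)
  expect_true(all(diff(gaps) > 0))
})
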