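test_that("nuclei segmentation recovers well-separated synthetic nuclei", {
  f <- render_field(phenotype_spec("diffuse"), cells = 5, size = 128,
                    seed = 21)
  lab <- segment_nuclei(f$dna)
  expect_equal(max(lab), 5L)
  expect_identical(sort(unique(as.vector(lab))), 0:5)  # contiguous labels

  blank <- matrix(0, 64, 64)
  expect_equal(max(segment_nuclei(blank)), 0L)

  # two merged blobs stay one object without declumping
  m <- matrix(0, 64, 64)
  xs <- matrix(rep(1:64, 64), 64); ys <- t(xs)
  m[(xs - 28)^2 + (ys - 32)^2 <= 36] <- 1
  m[(xs - 36)^2 + (ys - 32)^2 <= 36] <- 1
  expect_equal(max(segment_nuclei(m)), 1L)
})

test_that("distance-N expansion matches the per-pixel nearest-nucleus oracle", {
  lab <- matrix(0L, 48, 48)
  lab[8:12, 8:12] <- 1L
  lab[30:36, 25:31] <- 2L
  lab[10:13, 35:39] <- 3L
  n <- 7
  out <- expand_cells_distance_n(lab, n)
  pixlist <- lapply(1:3, function(k) which(lab == k, arr.ind = TRUE))
  oracle <- matrix(0L, 48, 48)
  for (r in 1:48) for (c in 1:48) {
    d2s <- vapply(pixlist, function(px) min((px[, 1] - r)^2 + (px[, 2] - c)^2),
                  0)
    k <- which.min(d2s)  # ties to lower label
    if (d2s[k] <= n^2) oracle[r, c] <- k
  }
  expect_identical(out, oracle)

  # partition: disjoint regions, each containing its nucleus
  for (k in 1:3) expect_true(all(out[lab == k] == k))
  expect_identical(expand_cells_distance_n(lab, 0), lab)
  expect_error(expand_cells_distance_n(lab, -1), ">= 0")

  # abutting regions split at the perpendicular bisector
  two <- matrix(0L, 40, 40)
  two[20, 10] <- 1L; two[20, 20] <- 2L
  ex <- expand_cells_distance_n(two, 10)
  expect_true(all(ex[, 1:15][ex[, 1:15] > 0] == 1L))
  expect_true(all(ex[, 16:40][ex[, 16:40] > 0] == 2L))

  # geometry: disk nucleus radius 5 expanded by 10 is a radius-15 disk
  disk <- matrix(0L, 64, 64)
  xs <- matrix(rep(1:64, 64), 64); ys <- t(xs)
  disk[(xs - 32)^2 + (ys - 32)^2 <= 25] <- 1L
  area <- sum(expand_cells_distance_n(disk, 10) == 1L)
  expect_lt(abs(area - pi * 15^2) / (pi * 15^2), 0.03)
})

test_that("object measurements have exactly 237 columns with sane degeneracies", {
  man <- segmentation_manifest()
  expect_equal(nrow(man), 237L)
  expect_setequal(unique(man$category),
                  c("granularity", "neighbors", "intensity",
                    "intensity_distribution", "texture"))

  f <- render_field(phenotype_spec("puncta", puncta_count = 10), cells = 6,
                    size = 128, seed = 31)
  nuc <- segment_nuclei(f$dna)
  cells <- expand_cells_distance_n(nuc, 10)
  obj <- measure_objects(cells, f$probe, nuc)
  expect_equal(ncol(obj), 238L)  # object id + 237
  expect_equal(nrow(obj), max(cells))
  expect_true(all(is.finite(as.matrix(obj[, -1]))))

  # blank probe channel: intensity measurements vanish
  obj0 <- measure_objects(cells, matrix(0, 128, 128), nuc)
  int_cols <- man$feature_name[man$category == "intensity"]
  expect_true(all(as.matrix(obj0[int_cols]) == 0))

  # single object: no neighbours
  single <- matrix(0L, 64, 64)
  single[30:40, 30:40] <- 1L
  obj1 <- measure_objects(single, matrix(0.5, 64, 64))
  expect_equal(obj1$neighbors_n_adjacent, 0)
  expect_equal(obj1$neighbors_d_first, 0)

  # zero objects: empty table, 237 columns
  none <- measure_objects(matrix(0L, 64, 64), matrix(0, 64, 64))
  expect_equal(dim(none), c(0L, 238L))
})

test_that("per-image aggregation is the column mean and flags empty images", {
  f <- render_field(phenotype_spec("diffuse"), cells = 4, size = 96,
                    seed = 41)
  nuc <- segment_nuclei(f$dna)
  cells <- expand_cells_distance_n(nuc, 8)
  obj <- measure_objects(cells, f$probe, nuc)
  agg <- aggregate_image(obj)
  expect_length(agg, 237L)
  expect_false(attr(agg, "empty_image"))
  expect_equal(unname(agg[1]), mean(obj[[2]]))

  # duplicating every object leaves the mean unchanged
  agg2 <- aggregate_image(dplyr::bind_rows(obj, obj))
  expect_equal(as.numeric(agg2), as.numeric(agg))

  one <- obj[1, ]
  expect_equal(as.numeric(aggregate_image(one)),
               as.numeric(unlist(one[, -1])))

  empty <- measure_objects(matrix(0L, 64, 64), matrix(0, 64, 64))
  agge <- aggregate_image(empty)
  expect_true(attr(agge, "empty_image"))
  expect_true(all(is.na(agge)))
})
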