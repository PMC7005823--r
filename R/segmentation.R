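#' Segmentation-based comparator pipeline
#'
#' The comparator to the whole-image bank: nuclei are detected in the DNA
#' channel, cell regions are approximated by expanding each nucleus outward
#' a fixed number of pixels (nearest-nucleus assignment, "distance-N"), and
#' 237 per-object measurements are taken from the probe channel inside each
#' cell region, then aggregated to per-image means.
#'
#' @name segmentation
NULL

SEG_TEXTURE_SCALES <- 1:6
SEG_GRANULARITY_SCALES <- 1:16
SEG_RADIAL_BINS <- 8L

#' Detect nuclei in the DNA channel
#'
#' Gaussian smoothing, Otsu threshold, hole filling, connected-component
#' labelling and a minimum-area filter. No declumping is attempted: merged
#' nuclei stay one object.
#'
#' @param dna DNA-channel matrix in \[0, 1\].
#' @param sigma Gaussian smoothing sigma (px).
#' @param min_area minimum object area (px).
#' @return integer label matrix (0 = background, labels contiguous 1..n).
#' @export
segment_nuclei <- function(dna, sigma = 2, min_area = 20L) {
  assert_image(dna, min_side = 8L, arg = "dna")
  if (max(dna) - min(dna) < 1e-6) {
    return(matrix(0L, nrow(dna), ncol(dna)))
  }
  sm <- unclass(EBImage::gblur(rescale01(dna), sigma = sigma))
  thr <- EBImage::otsu(sm, range = c(0, 1))
  mask <- EBImage::fillHull(sm > thr)
  lab <- unclass(EBImage::bwlabel(mask))
  relabel_filtered(lab, min_area)
}

relabel_filtered <- function(lab, min_area) {
  n <- max(lab)
  if (n == 0) return(matrix(0L, nrow(lab), ncol(lab)))
  areas <- tabulate(lab[lab > 0], n)
  keep <- which(areas >= min_area)
  map <- integer(n)
  map[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0
  out[pos] <- map[lab[pos]]
  out
}

#' Approximate cell regions by fixed-distance expansion
#'
#' Each nucleus is expanded outward by up to `n` pixels. Contested pixels go
#' to the nucleus whose nearest pixel is closest in exact Euclidean
#' distance; ties go to the lower label. Cell regions are pairwise disjoint
#' and each contains its nucleus.
#'
#' @param nuclei integer label matrix from [segment_nuclei()].
#' @param n maximum expansion distance in pixels (>= 0).
#' @return integer label matrix of cell regions.
#' @export
expand_cells_distance_n <- function(nuclei, n = 10) {
  if (n < 0) abort("Expansion distance `n` must be >= 0.")
  n_obj <- max(nuclei)
  out <- matrix(as.integer(nuclei), nrow(nuclei))
  if (n_obj == 0 || n == 0) return(out)
  nr <- nrow(nuclei); nc <- ncol(nuclei)
  best_d2 <- matrix(Inf, nr, nc)
  best_lab <- matrix(0L, nr, nc)
  n2 <- n^2
  for (k in seq_len(n_obj)) {
    pix <- which(nuclei == k, arr.ind = TRUE)
    bdry <- boundary_pixels(nuclei, pix, k)
    r0 <- max(1L, min(pix[, 1]) - ceiling(n)); r1 <- min(nr, max(pix[, 1]) + ceiling(n))
    c0 <- max(1L, min(pix[, 2]) - ceiling(n)); c1 <- min(nc, max(pix[, 2]) + ceiling(n))
    rr <- r0:r1; cc <- c0:c1
    # min squared distance from every bbox pixel to the nucleus boundary
    dr2 <- outer(rr, bdry[, 1], function(a, b) (a - b)^2)
    dc2 <- outer(cc, bdry[, 2], function(a, b) (a - b)^2)
    m <- length(rr); q <- length(cc)
    d2 <- matrix(Inf, m, q)
    for (b in seq_len(nrow(bdry))) {
      d2 <- pmin(d2, outer(dr2[, b], dc2[, b], "+"))
    }
    sub_best <- best_d2[rr, cc, drop = FALSE]
    upd <- d2 < sub_best & d2 <= n2
    if (any(upd)) {
      sub_lab <- best_lab[rr, cc, drop = FALSE]
      sub_best[upd] <- d2[upd]
      sub_lab[upd] <- k
      best_d2[rr, cc] <- sub_best
      best_lab[rr, cc] <- sub_lab
    }
  }
  grow <- out == 0L & best_lab > 0L
  out[grow] <- best_lab[grow]
  out
}

# 8-boundary pixels of object k (pixels with at least one non-k neighbour or
# on the image border); nearest object pixel to any outside point is always
# among these.
boundary_pixels <- function(lab, pix, k) {
  nr <- nrow(lab); nc <- ncol(lab)
  is_b <- vapply(seq_len(nrow(pix)), function(i) {
    r <- pix[i, 1]; c <- pix[i, 2]
    if (r == 1L || r == nr || c == 1L || c == nc) return(TRUE)
    any(lab[(r - 1L):(r + 1L), (c - 1L):(c + 1L)] != k)
  }, TRUE)
  pix[is_b, , drop = FALSE]
}

#' The 237-measurement manifest of the segmentation pipeline
#'
#' Categories and widths: granularity spectrum at 16 opening scales (16);
#' object neighbourhood (8); object intensity (33); nucleus-centred radial
#' intensity distribution, 8 bins x 3 statistics (24); direction-averaged
#' co-occurrence texture at 6 scales, 13 features x mean/range (156).
#'
#' @return tibble with `feature_name` and `category`, 237 rows.
#' @export
segmentation_manifest <- function() {
  cache_get_or("seg_manifest", function() {
    nm <- c(
      sprintf("granularity_s%d", SEG_GRANULARITY_SCALES),
      paste0("neighbors_", c("n_adjacent", "pct_perimeter_touching",
                             "d_first", "d_second", "d_mean", "d_sd",
                             "d_max", "n_within_40px")),
      paste0("intensity_", c(
        "integrated", "mean", "median", "sd", "mad", "min", "max",
        "q05", "q10", "q25", "q75", "q90", "q95", "skew", "kurt",
        "energy", "entropy", "edge_integrated", "edge_mean", "edge_sd",
        "edge_min", "edge_max", "mass_displacement", "cm_offset_x",
        "cm_offset_y", "range", "iqr", "cv", "upper_decile_mean",
        "lower_decile_mean", "frac_high", "top5_mean", "q99")),
      as.vector(t(outer(sprintf("radial_bin%d", seq_len(SEG_RADIAL_BINS)),
                        c("frac_at_d", "mean_frac", "cv"), paste, sep = "_"))),
      unlist(lapply(SEG_TEXTURE_SCALES, function(s) {
        base <- c("asm", "contrast", "correlation", "variance", "idm",
                  "sum_avg", "sum_var", "sum_ent", "entropy", "diff_var",
                  "diff_ent", "icm1", "icm2")
        c(sprintf("texture_s%d_%s_mean", s, base),
          sprintf("texture_s%d_%s_range", s, base))
      })))
    cat_of <- c(rep("granularity", 16), rep("neighbors", 8),
                rep("intensity", 33), rep("intensity_distribution", 24),
                rep("texture", 156))
    out <- tibble::tibble(feature_name = nm, category = cat_of)
    stopifnot(nrow(out) == 237L, !anyDuplicated(out$feature_name))
    out
  })
}

# GLCM restricted to pixel pairs inside a mask
glcm_masked <- function(q, mask, G, dr, dc) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- seq_len(nr - abs(dr)); c1 <- seq_len(nc - abs(dc))
  if (dr < 0) r1 <- r1 - dr
  if (dc < 0) c1 <- c1 - dc
  ok <- mask[r1, c1] & mask[r1 + dr, c1 + dc]
  if (!any(ok)) return(NULL)
  i <- q[r1, c1][ok]
  j <- q[r1 + dr, c1 + dc][ok]
  counts <- tabulate((i - 1L) * G + j, G * G)
  M <- matrix(counts, G, G, byrow = TRUE)
  M <- M + t(M)
  M / sum(M)
}

#' Per-object measurements within cell regions
#'
#' @param cells cell-region label matrix from [expand_cells_distance_n()].
#' @param probe probe-channel matrix (same shape).
#' @param nuclei optional nucleus label matrix; radial distribution bins are
#'   centred on the nucleus centroid when given, else on the cell centroid.
#' @return tibble with one row per object and the 237 manifest columns (plus
#'   a leading `object` id column). Zero objects give a 0-row table.
#' @export
measure_objects <- function(cells, probe, nuclei = NULL) {
  stopifnot(all(dim(cells) == dim(probe)))
  man <- segmentation_manifest()
  n_obj <- max(cells)
  if (n_obj == 0) {
    empty <- matrix(numeric(0), 0, 237,
                    dimnames = list(NULL, man$feature_name))
    return(dplyr::bind_cols(tibble::tibble(object = integer(0)),
                            tibble::as_tibble(empty)))
  }
  opened <- lapply(SEG_GRANULARITY_SCALES, function(s) {
    unclass(EBImage::opening(probe, EBImage::makeBrush(2L * s + 1L, "disc")))
  })
  centroids <- t(vapply(seq_len(n_obj), function(k) {
    src <- if (!is.null(nuclei) && any(nuclei == k)) nuclei else cells
    pix <- which(src == k, arr.ind = TRUE)
    c(mean(pix[, 1]), mean(pix[, 2]))
  }, numeric(2)))

  rows <- lapply(seq_len(n_obj), function(k) {
    measure_one_object(k, cells, probe, opened, centroids)
  })
  dplyr::bind_cols(tibble::tibble(object = seq_len(n_obj)),
                   dplyr::bind_rows(lapply(rows, tibble::as_tibble_row)))
}

measure_one_object <- function(k, cells, probe, opened, centroids) {
  mask <- cells == k
  v <- probe[mask]
  area <- length(v)
  tot <- sum(v)

  # granularity: intensity removed by each extra opening scale
  sums <- vapply(opened, function(o) sum(o[mask]), 0)
  prev <- c(tot, sums[-length(sums)])
  gran <- if (tot > 0) pmax(prev - sums, 0) / tot else rep(0, length(sums))
  names(gran) <- sprintf("granularity_s%d", SEG_GRANULARITY_SCALES)

  # neighbours
  n_obj <- nrow(centroids)
  pix <- which(mask, arr.ind = TRUE)
  nb <- neighbor_stats(k, cells, pix, centroids)

  # intensity
  q <- quantile(v, c(0.05, 0.1, 0.25, 0.75, 0.9, 0.95))
  edge_v <- probe[boundary_pixels(cells, pix, k)]
  cm <- if (tot > 0) {
    c(sum(pix[, 1] * v), sum(pix[, 2] * v)) / tot
  } else unname(colMeans(pix))
  geo <- unname(colMeans(pix))
  hi_thr <- mean(v) + 2 * sd(v)
  top5 <- mean(sort(v, decreasing = TRUE)[seq_len(max(1, ceiling(0.05 * area)))])
  hist256 <- tabulate(pmin(floor(v * 256) + 1L, 256L), 256L)
  intensity <- c(
    integrated = tot, mean = mean(v), median = median(v), sd = sd(v),
    mad = mad(v), min = min(v), max = max(v),
    q05 = unname(q[1]), q10 = unname(q[2]), q25 = unname(q[3]),
    q75 = unname(q[4]), q90 = unname(q[5]), q95 = unname(q[6]),
    skew = skewness(v), kurt = kurtosis(v), energy = mean(v^2),
    entropy = shannon_entropy(hist256 / area),
    edge_integrated = sum(edge_v), edge_mean = mean(edge_v),
    edge_sd = sd(edge_v), edge_min = min(edge_v), edge_max = max(edge_v),
    mass_displacement = sqrt(sum((cm - geo)^2)),
    cm_offset_x = cm[1] - geo[1], cm_offset_y = cm[2] - geo[2],
    range = diff(range(v)), iqr = unname(q[4] - q[3]),
    cv = if (mean(v) > 0) sd(v) / mean(v) else 0,
    upper_decile_mean = mean(v[v >= q[5]]),
    lower_decile_mean = mean(v[v <= q[2]]),
    frac_high = mean(v > hi_thr), top5_mean = top5,
    q99 = unname(quantile(v, 0.99)))
  names(intensity) <- paste0("intensity_", names(intensity))

  # radial intensity distribution, centred on the (nucleus) centroid
  ctr <- centroids[k, ]
  d <- sqrt((pix[, 1] - ctr[1])^2 + (pix[, 2] - ctr[2])^2)
  dmax <- max(d)
  bin <- if (dmax > 0) pmin(floor(d / dmax * SEG_RADIAL_BINS) + 1L,
                            SEG_RADIAL_BINS) else rep(1L, area)
  radial <- unlist(lapply(seq_len(SEG_RADIAL_BINS), function(b) {
    inb <- bin == b
    frac_at_d <- if (tot > 0) sum(v[inb]) / tot else 0
    pix_frac <- mean(inb)
    mean_frac <- if (pix_frac > 0) frac_at_d / pix_frac else 0
    cvb <- if (any(inb) && mean(v[inb]) > 0) sd(v[inb]) / mean(v[inb]) else 0
    stats::setNames(c(frac_at_d, mean_frac, if (is.finite(cvb)) cvb else 0),
                    sprintf("radial_bin%d_%s", b, c("frac_at_d", "mean_frac", "cv")))
  }))

  # texture: direction-averaged co-occurrence inside the object, 6 scales
  r0 <- min(pix[, 1]); r1 <- max(pix[, 1])
  c0 <- min(pix[, 2]); c1 <- max(pix[, 2])
  sub <- probe[r0:r1, c0:c1, drop = FALSE]
  smask <- mask[r0:r1, c0:c1, drop = FALSE]
  G <- 32L
  rng <- range(sub[smask])
  qs <- if (diff(rng) > 0) {
    matrix(pmin(floor((sub - rng[1]) / diff(rng) * G) + 1L, G), nrow(sub))
  } else matrix(1L, nrow(sub), ncol(sub))
  texture <- unlist(lapply(SEG_TEXTURE_SCALES, function(s) {
    dirs <- list(c(0L, s), c(s, s), c(s, 0L), c(s, -s))
    per_dir <- lapply(dirs, function(dd) {
      P <- glcm_masked(qs, smask, G, dd[1], dd[2])
      if (is.null(P)) NULL else haralick13(P)
    })
    per_dir <- per_dir[!vapply(per_dir, is.null, TRUE)]
    base <- c("asm", "contrast", "correlation", "variance", "idm", "sum_avg",
              "sum_var", "sum_ent", "entropy", "diff_var", "diff_ent",
              "icm1", "icm2")
    if (!length(per_dir)) {
      m <- stats::setNames(rep(0, 13), base); r <- m
    } else {
      M <- do.call(cbind, per_dir)
      m <- rowMeans(M)
      r <- apply(M, 1, function(x) diff(range(x)))
    }
    stats::setNames(c(m, r), c(sprintf("texture_s%d_%s_mean", s, base),
                               sprintf("texture_s%d_%s_range", s, base)))
  }))

  finite_or0(c(gran, nb, intensity, radial, texture))
}

neighbor_stats <- function(k, cells, pix, centroids) {
  n_obj <- nrow(centroids)
  nr <- nrow(cells); nc <- ncol(cells)
  bdry <- boundary_pixels(cells, pix, k)
  touching <- integer(0)
  perim_touch <- 0L
  for (i in seq_len(nrow(bdry))) {
    r <- bdry[i, 1]; c <- bdry[i, 2]
    rs <- max(1L, r - 1L):min(nr, r + 1L)
    cs <- max(1L, c - 1L):min(nc, c + 1L)
    nbs <- cells[rs, cs]
    other <- nbs[nbs != 0L & nbs != k]
    if (length(other)) {
      perim_touch <- perim_touch + 1L
      touching <- c(touching, other)
    }
  }
  touching <- unique(touching)
  ds <- if (n_obj > 1) {
    sqrt((centroids[-k, 1] - centroids[k, 1])^2 +
         (centroids[-k, 2] - centroids[k, 2])^2)
  } else numeric(0)
  sds <- sort(ds)
  c(neighbors_n_adjacent = length(touching),
    neighbors_pct_perimeter_touching = if (nrow(bdry)) perim_touch / nrow(bdry) else 0,
    neighbors_d_first = if (length(sds) >= 1) sds[1] else 0,
    neighbors_d_second = if (length(sds) >= 2) sds[2] else 0,
    neighbors_d_mean = if (length(ds)) mean(ds) else 0,
    neighbors_d_sd = if (length(ds) > 1) sd(ds) else 0,
    neighbors_d_max = if (length(ds)) max(ds) else 0,
    neighbors_n_within_40px = sum(ds <= 40))
}

#' Aggregate per-object measurements to a per-image vector
#'
#' Column-wise arithmetic mean. An empty object table yields an all-`NA`
#' vector flagged with `attr(., "empty_image") = TRUE`; downstream embedding
#' drops flagged images with a message.
#'
#' @param objects an object table from [measure_objects()].
#' @return named numeric vector of length 237 (attribute `empty_image`).
#' @export
aggregate_image <- function(objects) {
  man <- segmentation_manifest()
  feats <- objects[man$feature_name]
  if (!nrow(feats)) {
    out <- stats::setNames(rep(NA_real_, 237), man$feature_name)
    attr(out, "empty_image") <- TRUE
    return(out)
  }
  out <- colMeans(as.matrix(feats))
  attr(out, "empty_image") <- FALSE
  out
}

#' One-call segmentation-based feature vector for a field
#'
#' @param dna,probe the two channel matrices.
#' @param n_expand distance-N expansion in pixels.
#' @return named vector: `n_objects` followed by the 237 aggregated
#'   measurements (NA when no object was found).
#' @export
extract_segmentation <- function(dna, probe, n_expand = 10) {
  nuclei <- segment_nuclei(dna)
  cells <- expand_cells_distance_n(nuclei, n_expand)
  objects <- measure_objects(cells, probe, nuclei = nuclei)
  agg <- aggregate_image(objects)
  c(n_objects = max(cells), agg)
}
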