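#' Whole-image morphological feature families
#'
#' Each family maps one image plane to a fixed-length named sub-vector.
#' Texture families use a 32-level quantisation of the contrast-stretched
#' plane; Haralick features are direction-averaged (mean and range over the
#' four co-occurrence directions) and Zernike features are moment magnitudes,
#' so both are invariant to exact 90-degree grid rotations of the plane.
#' Degenerate statistics (e.g. the correlation of a constant plane) are
#' imputed as 0 so every extraction is finite.
#'
#' @name charm-families
NULL

FAMILY_LENGTHS <- c(
  pixel_stats = 12L, multiscale_histograms = 24L, haralick = 26L,
  gabor = 14L, tamura = 6L, zernike = 25L, chebyshev_stats = 32L,
  chebyshev_fourier = 32L, radon_stats = 12L, edge_stats = 28L,
  otsu_object_stats = 10L, moments_comb = 16L)

#' Extract one feature family from an image plane
#'
#' @param plane numeric matrix (any size >= 8 x 8), typically one plane of
#'   [transform_stack()].
#' @param family family name, one of `names(phenoprobe:::FAMILY_LENGTHS)`.
#' @return named numeric vector of the family's fixed length.
#' @examples
#' extract_family(matrix(runif(64 * 64), 64), "pixel_stats")
#' @export
extract_family <- function(plane, family) {
  if (!is.matrix(plane) || !is.numeric(plane)) {
    abort("`plane` must be a numeric 2D matrix.")
  }
  if (!family %in% names(FAMILY_LENGTHS)) {
    abort(sprintf("Unknown feature family '%s'. Valid families: %s.",
                  family, paste(names(FAMILY_LENGTHS), collapse = ", ")))
  }
  fn <- switch(family,
    pixel_stats = family_pixel_stats,
    multiscale_histograms = family_multiscale_histograms,
    haralick = family_haralick,
    gabor = family_gabor,
    tamura = family_tamura,
    zernike = family_zernike,
    chebyshev_stats = family_chebyshev_stats,
    chebyshev_fourier = family_chebyshev_fourier,
    radon_stats = family_radon_stats,
    edge_stats = family_edge_stats,
    otsu_object_stats = family_otsu_object_stats,
    moments_comb = family_moments_comb)
  v <- finite_or0(fn(plane))
  stopifnot(length(v) == FAMILY_LENGTHS[[family]])
  v
}

family_pixel_stats <- function(p) {
  v <- as.vector(p)
  h <- tabulate(pmin(floor(v * 256) + 1L, 256L), 256L)
  c(mean = mean(v), sd = sd(v), skewness = skewness(v),
    kurtosis = kurtosis(v), min = min(v), max = max(v),
    median = median(v), mad = mad(v),
    p10 = unname(quantile(v, 0.1)), p90 = unname(quantile(v, 0.9)),
    energy = mean(v^2), entropy = shannon_entropy(h / length(v)))
}

family_multiscale_histograms <- function(p) {
  v <- as.vector(p)
  out <- unlist(lapply(c(3L, 5L, 7L, 9L), function(nb) {
    h <- tabulate(pmin(floor(v * nb) + 1L, nb), nb) / length(v)
    stats::setNames(h, sprintf("h%d_bin%d", nb, seq_len(nb)))
  }))
  out
}

# ---- Haralick ----------------------------------------------------------

glcm <- function(q, G, dr, dc) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- seq_len(nr - abs(dr)); c1 <- seq_len(nc - abs(dc))
  if (dr < 0) r1 <- r1 - dr
  if (dc < 0) c1 <- c1 - dc
  i <- q[r1, c1]
  j <- q[r1 + dr, c1 + dc]
  counts <- tabulate((i - 1L) * G + j, G * G)
  M <- matrix(counts, G, G, byrow = TRUE)
  M <- M + t(M)
  M / sum(M)
}

haralick13 <- function(P) {
  G <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(seq_len(G) * px)
  sig2 <- sum((seq_len(G) - mu)^2 * px)
  sig <- sqrt(sig2)
  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sig > 0) (sum(i * j * P) - mu^2) / sig2 else 0
  variance <- sum((i - mu)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  # sum / difference distributions
  psum <- tapply(P, i + j, sum)
  ks <- as.numeric(names(psum))
  sum_avg <- sum(ks * psum)
  sum_var <- sum((ks - sum_avg)^2 * psum)
  sum_ent <- shannon_entropy(psum)
  pdiff <- tapply(P, abs(i - j), sum)
  kd <- as.numeric(names(pdiff))
  diff_var <- sum((kd - sum(kd * pdiff))^2 * pdiff)
  diff_ent <- shannon_entropy(pdiff)
  entropy <- shannon_entropy(P)
  hx <- shannon_entropy(px)
  pxy <- outer(px, px)
  pos <- P > 0 & pxy > 0
  hxy1 <- -sum(P[pos] * log2(pxy[pos]))
  hxy2 <- shannon_entropy(pxy)
  icm1 <- if (hx > 0) (entropy - hxy1) / hx else 0
  icm2_arg <- 1 - exp(-2 * (hxy2 - entropy))
  icm2 <- if (icm2_arg > 0) sqrt(icm2_arg) else 0
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_avg = sum_avg, sum_var = sum_var,
    sum_ent = sum_ent, entropy = entropy, diff_var = diff_var,
    diff_ent = diff_ent, icm1 = icm1, icm2 = icm2)
}

family_haralick <- function(p, G = 32L) {
  q <- matrix(pmin(floor(rescale01(p) * G) + 1L, G), nrow(p))
  dirs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  per_dir <- vapply(dirs, function(d) haralick13(glcm(q, G, d[1], d[2])),
                    numeric(13))
  m <- rowMeans(per_dir)
  r <- apply(per_dir, 1, function(x) diff(range(x)))
  stats::setNames(c(m, r),
                  c(paste0(names(m), "_mean"), paste0(names(m), "_range")))
}

# ---- Gabor -------------------------------------------------------------

gabor_kernel <- function(freq, theta, size = 17L) {
  half <- (size - 1) / 2
  xs <- matrix(rep(-half:half, size), size)
  ys <- t(xs)
  xr <- xs * cos(theta) + ys * sin(theta)
  yr <- -xs * sin(theta) + ys * cos(theta)
  sigma <- 0.56 / freq
  env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
  list(re = env * cos(2 * pi * freq * xr),
       im = env * sin(2 * pi * freq * xr))
}

GABOR_BANK <- list(
  c(0.08, 0), c(0.08, pi / 4), c(0.08, pi / 2),
  c(0.16, 0), c(0.16, pi / 4), c(0.16, pi / 2),
  c(0.24, 0))

family_gabor <- function(p) {
  out <- unlist(lapply(seq_along(GABOR_BANK), function(k) {
    fk <- GABOR_BANK[[k]]
    kern <- cache_get_or(sprintf("gabor_%d", k),
                         function() gabor_kernel(fk[1], fk[2]))
    mag <- sqrt(unclass(EBImage::filter2(p, kern$re))^2 +
                unclass(EBImage::filter2(p, kern$im))^2)
    stats::setNames(c(mean(mag), sd(mag)),
                    sprintf("g%d_%s", k, c("mean", "sd")))
  }))
  out
}

# ---- Tamura ------------------------------------------------------------

# mean over a (2h+1)-window clamped at the borders, via integral image
box_mean <- function(p, h) {
  nr <- nrow(p); nc <- ncol(p)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1, -1] <- apply(apply(p, 2, cumsum), 1, cumsum) |> t()
  r0 <- pmax(seq_len(nr) - h - 1L, 0L) + 1L
  r1 <- pmin(seq_len(nr) + h, nr) + 1L
  c0 <- pmax(seq_len(nc) - h - 1L, 0L) + 1L
  c1 <- pmin(seq_len(nc) + h, nc) + 1L
  tot <- S[r1, c1] - S[r0, c1] - S[r1, c0] + S[r0, c0]
  area <- outer(r1 - r0, c1 - c0)
  tot / area
}

family_tamura <- function(p) {
  scales <- 1:5
  npx <- length(p)
  E <- matrix(0, npx, length(scales))
  for (k in scales) {
    s <- 2L^(k - 1L)
    # scales whose window exceeds the plane contribute nothing
    if (2L * s >= min(dim(p))) next
    A <- box_mean(p, s)
    eh <- matrix(0, nrow(p), ncol(p))
    ev <- matrix(0, nrow(p), ncol(p))
    rr <- (s + 1):(nrow(p) - s); cc <- (s + 1):(ncol(p) - s)
    eh[rr, ] <- abs(A[rr + s, ] - A[rr - s, ])
    ev[, cc] <- abs(A[, cc + s] - A[, cc - s])
    E[, k] <- pmax(eh, ev)
  }
  best <- max.col(E, ties.method = "first")
  coarseness <- mean(2^best)
  bh <- tabulate(pmin(best, 5L), 5L)
  bh <- c(bh[1] + bh[2], bh[3], bh[4] + bh[5]) / length(best)
  v <- as.vector(p)
  k4 <- mean((v - mean(v))^4) / max(sd(v)^4, .Machine$double.eps)
  contrast <- if (sd(v) > 0) sd(v) / k4^0.25 else 0
  g <- sobel_gradients(p)
  wts <- as.vector(sqrt(g$gx^2 + g$gy^2))
  ang <- atan2(as.vector(g$gy), as.vector(g$gx)) %% pi
  hh <- rep(0, 16)
  if (sum(wts) > 0) {
    bins <- pmin(floor(ang / pi * 16) + 1L, 16L)
    agg <- rowsum(wts, bins)
    hh[as.integer(rownames(agg))] <- agg
    hh <- hh / sum(hh)
  }
  hn <- if (sum(hh) > 0) hh else rep(1 / 16, 16)
  directionality <- 1 - shannon_entropy(hn) / log2(16)
  c(coarseness = coarseness / 32, coarse_fine = bh[1], coarse_mid = bh[2],
    coarse_large = bh[3], contrast = contrast,
    directionality = directionality)
}

# ---- Zernike -----------------------------------------------------------

zernike_nm <- function(max_order = 8L) {
  nm <- list()
  for (n in 0:max_order) for (m in seq(n %% 2, n, 2)) {
    nm[[length(nm) + 1L]] <- c(n, m)
  }
  nm
}

zernike_basis <- function(size, max_order = 8L) {
  cache_get_or(sprintf("zern_%d_%d", size, max_order), function() {
    ctr <- (size + 1) / 2
    R <- size / 2
    xs <- matrix(rep(seq_len(size), size), size)
    ys <- t(xs)
    rho <- sqrt((xs - ctr)^2 + (ys - ctr)^2) / R
    keep <- which(rho <= 1)
    th <- atan2(ys - ctr, xs - ctr)[keep]
    rh <- rho[keep]
    nm <- zernike_nm(max_order)
    basis <- vapply(nm, function(p) {
      n <- p[1]; m <- p[2]
      rad <- rep(0, length(rh))
      for (s in 0:((n - m) / 2)) {
        coef <- (-1)^s * factorial(n - s) /
          (factorial(s) * factorial((n + m) / 2 - s) *
             factorial((n - m) / 2 - s))
        rad <- rad + coef * rh^(n - 2 * s)
      }
      complex(real = rad * cos(m * th), imaginary = -rad * sin(m * th))
    }, complex(length(keep)))
    names_nm <- vapply(nm, function(p) sprintf("z%d_%d", p[1], p[2]), "")
    list(keep = keep, basis_t = t(basis), names = names_nm)
  })
}

family_zernike <- function(p) {
  # square support: centre crop to the short side so the unit disk fits
  side <- min(dim(p))
  r0 <- (nrow(p) - side) %/% 2L
  c0 <- (ncol(p) - side) %/% 2L
  sq <- p[r0 + seq_len(side), c0 + seq_len(side)]
  zb <- zernike_basis(side)
  f <- as.vector(sq)[zb$keep]
  mags <- Mod(zb$basis_t %*% f) / length(zb$keep)
  stats::setNames(as.vector(mags), zb$names)
}

# ---- Chebyshev statistics ---------------------------------------------

coef_histogram <- function(C, nbins = 32L) {
  v <- rescale01(matrix(as.vector(C), 1))
  h <- tabulate(pmin(floor(as.vector(v) * nbins) + 1L, nbins), nbins)
  stats::setNames(h / length(v), sprintf("bin%d", seq_len(nbins)))
}

family_chebyshev_stats <- function(p) {
  coef_histogram(chebyshev_coefficients(p, order = 20L))
}

family_chebyshev_fourier <- function(p) {
  coef_histogram(chebyshev_coefficients(fourier_plane(p), order = 20L))
}

# ---- Radon projections -------------------------------------------------

family_radon_stats <- function(p) {
  projs <- list(
    deg0 = colSums(p), deg90 = rowSums(p),
    deg45 = as.vector(tapply(p, row(p) + col(p), sum)),
    deg135 = as.vector(tapply(p, row(p) - col(p), sum)))
  out <- unlist(lapply(names(projs), function(nm) {
    v <- projs[[nm]]
    v <- if (sum(v) > 0) v / sum(v) else v
    stats::setNames(c(sd(v), skewness(v), max(v)),
                    sprintf("%s_%s", nm, c("sd", "skew", "max")))
  }))
  out
}

# ---- Edge statistics ---------------------------------------------------

family_edge_stats <- function(p) {
  g <- sobel_gradients(p)
  mag <- sqrt(g$gx^2 + g$gy^2)
  v <- as.vector(mag)
  mv <- rescale01(mag)
  mh <- tabulate(pmin(floor(as.vector(mv) * 8) + 1L, 8L), 8L) / length(v)
  ang <- atan2(as.vector(g$gy), as.vector(g$gx)) %% pi
  wts <- v
  dh <- rep(0, 8)
  if (sum(wts) > 0) {
    bins <- pmin(floor(ang / pi * 8) + 1L, 8L)
    agg <- rowsum(wts, bins)
    dh[as.integer(rownames(agg))] <- agg
    dh <- dh / sum(dh)
  }
  thr <- if (max(v) > min(v)) EBImage::otsu(mv, range = c(0, 1)) else 1
  edge_fraction <- mean(as.vector(mv) > thr)
  resultant <- if (sum(wts) > 0) {
    Mod(sum(wts * exp(2i * ang))) / sum(wts)
  } else 0
  c(stats::setNames(c(mean(v), sd(v), skewness(v), kurtosis(v), median(v),
                      mad(v), max(v), mean(v^2)),
                    paste0("mag_", c("mean", "sd", "skew", "kurt", "median",
                                     "mad", "max", "energy"))),
    stats::setNames(mh, sprintf("maghist_bin%d", 1:8)),
    stats::setNames(dh, sprintf("dirhist_bin%d", 1:8)),
    edge_fraction = edge_fraction, orient_resultant = resultant,
    dominant_ratio = max(dh), direction_entropy = shannon_entropy(dh))
}

# ---- Otsu object statistics -------------------------------------------

family_otsu_object_stats <- function(p) {
  empty <- stats::setNames(rep(0, 10),
                           c("n_objects", "area_fraction", "mean_area",
                             "sd_area", "max_area", "min_area",
                             "largest_fraction", "centroid_sd_x",
                             "centroid_sd_y", "centroid_spread"))
  if (max(p) <= min(p)) return(empty)
  thr <- EBImage::otsu(rescale01(p), range = c(0, 1))
  mask <- rescale01(p) > thr
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0) return(empty)
  areas <- tabulate(lab[lab > 0], n)
  npix <- length(p)
  cx <- as.vector(rowsum(as.numeric(row(lab)[lab > 0]), lab[lab > 0])) / areas
  cy <- as.vector(rowsum(as.numeric(col(lab)[lab > 0]), lab[lab > 0])) / areas
  ctr <- (dim(p) + 1) / 2
  spread <- mean(sqrt((cx - ctr[1])^2 + (cy - ctr[2])^2)) / sqrt(sum(dim(p)^2))
  stats::setNames(
    c(n / 100, sum(areas) / npix, mean(areas) / npix, sd(areas) / npix,
      max(areas) / npix, min(areas) / npix, max(areas) / sum(areas),
      sd(cx) / nrow(p), sd(cy) / ncol(p), spread),
    names(empty))
}

# ---- Moments -----------------------------------------------------------

family_moments_comb <- function(p) {
  tot <- sum(p)
  if (tot <= 0) {
    nms <- c(sprintf("eta%d%d", c(2, 0, 1, 3, 0, 2, 1, 2, 4, 0, 3, 1),
                     c(0, 2, 1, 0, 3, 1, 2, 2, 0, 4, 1, 3)),
             paste0("hu", 1:4))
    return(stats::setNames(rep(0, 16), nms))
  }
  x <- row(p); y <- col(p)
  xb <- sum(x * p) / tot; yb <- sum(y * p) / tot
  dx <- x - xb; dy <- y - yb
  xp <- list(`0` = 1, `1` = dx, `2` = dx^2, `3` = dx^2 * dx, `4` = (dx^2)^2)
  yp <- list(`0` = 1, `1` = dy, `2` = dy^2, `3` = dy^2 * dy, `4` = (dy^2)^2)
  eta <- function(pp, qq) {
    sum(xp[[pp + 1L]] * yp[[qq + 1L]] * p) / tot^(1 + (pp + qq) / 2)
  }
  pairs <- list(c(2, 0), c(0, 2), c(1, 1), c(3, 0), c(0, 3), c(2, 1),
                c(1, 2), c(2, 2), c(4, 0), c(0, 4), c(3, 1), c(1, 3))
  etas <- vapply(pairs, function(pr) eta(pr[1], pr[2]), 0)
  names(etas) <- vapply(pairs, function(pr) sprintf("eta%d%d", pr[1], pr[2]), "")
  e <- as.list(etas)
  hu1 <- e$eta20 + e$eta02
  hu2 <- (e$eta20 - e$eta02)^2 + 4 * e$eta11^2
  hu3 <- (e$eta30 - 3 * e$eta12)^2 + (3 * e$eta21 - e$eta03)^2
  hu4 <- (e$eta30 + e$eta12)^2 + (e$eta21 + e$eta03)^2
  c(etas, hu1 = hu1, hu2 = hu2, hu3 = hu3, hu4 = hu4)
}
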