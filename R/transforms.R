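#' Image transform stack for whole-image feature extraction
#'
#' The feature bank computes its feature families not only on the raw image
#' but on a fixed stack of derived planes, so that texture/statistic families
#' see the image in the spatial, frequency, multiresolution and polynomial
#' domains. All planes are rescaled to \[0, 1\] (a constant plane maps to
#' zeros).
#'
#' Planes: `raw`; `fourier` (shifted log-magnitude spectrum); `wavelet_approx`
#' and `wavelet_detail` (single-level Haar approximation and combined detail
#' magnitude); `chebyshev` (order-20 Chebyshev polynomial reconstruction);
#' `edge` (Sobel gradient magnitude); and the compound path
#' `wavelet_fourier` (spectrum of the wavelet approximation).
#'
#' @param image numeric matrix, at least 64 x 64, finite values.
#' @return named list of numeric matrices.
#' @examples
#' planes <- transform_stack(matrix(runif(64 * 64), 64))
#' names(planes)
#' @export
transform_stack <- function(image) {
  assert_image(image, min_side = 64L)
  w <- haar_decompose(image)
  list(
    raw = rescale01(image),
    fourier = fourier_plane(image),
    wavelet_approx = rescale01(w$approx),
    wavelet_detail = rescale01(w$detail),
    chebyshev = rescale01(chebyshev_reconstruct(image, order = 20L)),
    edge = rescale01(sobel_magnitude(image)),
    wavelet_fourier = fourier_plane(w$approx)
  )
}

# Shifted log-magnitude spectrum; constant images keep a single nonzero
# (DC) coefficient before rescaling.
fourier_plane <- function(image) {
  mag <- Mod(stats::fft(image))
  mag <- fftshift2(mag)
  rescale01(log1p(mag))
}

fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(seq(floor(nr / 2) + 1, nr), seq_len(floor(nr / 2)))
  ci <- c(seq(floor(nc / 2) + 1, nc), seq_len(floor(nc / 2)))
  m[ri, ci]
}

# Single-level 2D Haar decomposition (even dimensions; odd trailing
# row/column dropped). Detail plane combines LH/HL/HH magnitudes so it is
# invariant to 90-degree grid rotations.
haar_decompose <- function(image) {
  nr <- nrow(image) - nrow(image) %% 2L
  nc <- ncol(image) - ncol(image) %% 2L
  x <- image[seq_len(nr), seq_len(nc)]
  odd_r <- seq(1L, nr, 2L); evn_r <- odd_r + 1L
  odd_c <- seq(1L, nc, 2L); evn_c <- odd_c + 1L
  a <- x[odd_r, odd_c]; b <- x[odd_r, evn_c]
  c_ <- x[evn_r, odd_c]; d <- x[evn_r, evn_c]
  ll <- (a + b + c_ + d) / 4
  lh <- (a - b + c_ - d) / 4
  hl <- (a + b - c_ - d) / 4
  hh <- (a - b - c_ + d) / 4
  list(approx = ll, detail = sqrt(lh^2 + hl^2 + hh^2))
}

chebyshev_basis <- function(n, order) {
  cache_get_or(sprintf("cheb_basis_%d_%d", n, order), function() {
    x <- seq(-1, 1, length.out = n)
    B <- matrix(0, n, order + 1L)
    B[, 1] <- 1
    if (order >= 1) B[, 2] <- x
    for (k in seq_len(order - 1L) + 1L) B[, k + 1L] <- 2 * x * B[, k] - B[, k - 1L]
    # pseudo-inverse for least-squares coefficient fit
    list(B = B, Binv = solve(crossprod(B), t(B)))
  })
}

chebyshev_coefficients <- function(image, order = 20L) {
  br <- chebyshev_basis(nrow(image), order)
  bc <- chebyshev_basis(ncol(image), order)
  br$Binv %*% image %*% t(bc$Binv)
}

chebyshev_reconstruct <- function(image, order = 20L) {
  C <- chebyshev_coefficients(image, order)
  br <- chebyshev_basis(nrow(image), order)
  bc <- chebyshev_basis(ncol(image), order)
  br$B %*% C %*% t(bc$B)
}

# Sobel gradients with circular boundary, via index shifts (no FFT);
# circular padding commutes with exact 90-degree grid rotations.
sobel_gradients <- function(image) {
  nr <- nrow(image); nc <- ncol(image)
  up <- c(nr, seq_len(nr - 1L)); dn <- c(seq_len(nr - 1L) + 1L, 1L)
  lf <- c(nc, seq_len(nc - 1L)); rt <- c(seq_len(nc - 1L) + 1L, 1L)
  # smooth along rows, difference along columns (and vice versa)
  sm_r <- image[up, ] + 2 * image + image[dn, ]
  gx <- sm_r[, rt] - sm_r[, lf]
  sm_c <- image[, lf] + 2 * image + image[, rt]
  gy <- sm_c[dn, ] - sm_c[up, ]
  list(gx = gx, gy = gy)
}

sobel_magnitude <- function(image) {
  g <- sobel_gradients(image)
  sqrt(g$gx^2 + g$gy^2)
}
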