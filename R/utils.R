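# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||%
#' @importFrom stats var sd median mad quantile cor prcomp rnorm rpois runif
#' @import tibble
NULL

# package-scoped cache for memoised numeric bases (zernike, chebyshev, tamura)
.pp_cache <- new.env(parent = emptyenv())

cache_get_or <- function(key, fn) {
  if (!is.null(.pp_cache[[key]])) return(.pp_cache[[key]])
  val <- fn()
  assign(key, val, envir = .pp_cache)
  val
}

#' Rescale a numeric array to the unit interval
#'
#' Constant arrays map to all zeros (there is no contrast to preserve).
#' @param x numeric matrix/array.
#' @return array of the same shape with values in \[0, 1\].
#' @keywords internal
rescale01 <- function(x) {
  rng <- range(x, finite = TRUE)
  if (!is.finite(rng[1]) || rng[2] - rng[1] <= 0) {
    return(array(0, dim = dim(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

assert_image <- function(x, min_side = 1L, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric 2D matrix.", arg))
  }
  if (any(!is.finite(x))) abort(sprintf("`%s` contains non-finite values.", arg))
  if (min(dim(x)) < min_side) {
    abort(sprintf("`%s` must be at least %d x %d pixels.", arg, min_side, min_side))
  }
  invisible(x)
}

# Stable 32-bit string hash (polynomial rolling hash); used to derive
# per-image RNG seeds so that adding probes never perturbs existing images.
stable_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

derive_seed <- function(master_seed, ...) {
  key <- paste(..., sep = "|")
  as.integer((as.numeric(master_seed) * 48271 + stable_hash(key)) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

skewness <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

kurtosis <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(0)
  mean((x - mean(x))^4) / s^4 - 3
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

finite_or0 <- function(x) {
  x[!is.finite(x)] <- 0
  x
}
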