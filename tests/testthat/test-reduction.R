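make_base <- function(n = 40, k = 6, seed = 1) {
  withr::with_seed(seed, {
    tbl <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * k), n)))
    names(tbl) <- sprintf("f%d", seq_len(k))
    tbl
  })
}

test_that("variance filter drops only low-variance columns", {
  tbl <- make_base()
  tbl$const <- 2.5
  res <- drop_low_variance(tbl)
  expect_equal(res$dropped$feature, "const")
  expect_false("const" %in% names(res$matrix))

  # no constant columns + zero threshold = identity
  res0 <- drop_low_variance(make_base(), variance_min = 0)
  expect_equal(nrow(res0$dropped), 0L)

  # hand-computed: var(c(1,1,1,1.001)) = 2.5e-7 < 1e-3
  tiny <- tibble::tibble(a = c(1, 1, 1, 1.001), b = c(0, 5, 2, 9))
  rest <- drop_low_variance(tiny, variance_min = 1e-3)
  expect_equal(rest$dropped$feature, "a")
  expect_equal(rest$dropped$statistic, 2.5e-7, tolerance = 1e-12)

  expect_error(drop_low_variance(tiny[1, ]), "2 rows")
})

test_that("greedy correlation filter keeps the first of a correlated group", {
  tbl <- make_base()
  tbl$dup <- tbl$f1
  res <- drop_correlated(tbl)
  expect_equal(res$dropped$feature, "dup")

  tbl2 <- make_base()
  tbl2$neg <- -tbl2$f2
  res2 <- drop_correlated(tbl2)
  expect_equal(res2$dropped$feature, "neg")  # |r| = 1 with earlier column

  # three mutually near-duplicate columns: first kept, later two dropped
  tbl3 <- withr::with_seed(9, {
    base <- rnorm(60)
    tibble::tibble(a = base + rnorm(60, sd = 0.05),
                   b = base + rnorm(60, sd = 0.05),
                   c = base + rnorm(60, sd = 0.05),
                   z = rnorm(60))
  })
  stopifnot(min(abs(cor(tbl3[1:3]))) > 0.99)
  res3 <- drop_correlated(tbl3)
  expect_setequal(res3$dropped$feature, c("b", "c"))
  expect_true(all(c("a", "z") %in% names(res3$matrix)))
})

test_that("VIF filter removes exact linear combinations", {
  tbl <- make_base()
  res <- drop_collinear(tbl)  # independent columns: all VIF ~ 1
  expect_equal(nrow(res$dropped), 0L)

  tbl$s <- tbl$f1 + tbl$f2
  res2 <- drop_collinear(tbl)
  expect_gte(nrow(res2$dropped), 1L)
  left <- as.matrix(res2$matrix)
  expect_true(all(phenoprobe:::ridge_vif(left) <= 10))

  one <- tibble::tibble(a = rnorm(10))
  res1 <- drop_collinear(one)  # single column: VIF 1 by convention
  expect_equal(nrow(res1$dropped), 0L)
})

test_that("the reduction pipeline resolves a crafted 10-column matrix to 6 with correct reasons", {
  tbl <- make_base(n = 40, k = 6, seed = 1)
  tbl$dup1 <- tbl$f1          # duplicated pair with f1
  tbl$sum23 <- tbl$f2 + tbl$f3  # exact linear combination
  tbl$c1 <- 1; tbl$c2 <- 3.7    # constants
  red <- reduce_features(tbl)
  expect_setequal(names(red), sprintf("f%d", 1:6))
  prov <- reduction_provenance(red)
  expect_equal(nrow(prov), 4L)
  expect_equal(prov$dropped_by[match(c("c1", "c2"), prov$feature)],
               c("variance", "variance"))
  expect_equal(prov$dropped_by[prov$feature == "dup1"], "correlation")
  expect_equal(prov$dropped_by[prov$feature == "sum23"], "collinearity")
})

test_that("reduction is idempotent, conservative, and row-order stable", {
  tbl <- make_base(n = 30, k = 8, seed = 3)
  tbl$dup <- tbl$f3
  tbl$cc <- 0
  tbl$image_id <- sprintf("i%02d", 1:30)
  red <- reduce_features(tbl)
  # conservation: retained + dropped = input features
  expect_equal(length(phenoprobe:::feature_columns(red)) +
                 nrow(reduction_provenance(red)),
               length(phenoprobe:::feature_columns(tbl)))
  # idempotence
  red2 <- reduce_features(tibble::as_tibble(red))
  expect_identical(names(red2), names(red))
  expect_equal(nrow(reduction_provenance(red2)), 0L)
  # permuting rows does not change the retained set
  perm <- withr::with_seed(5, tbl[sample(nrow(tbl)), ])
  redp <- reduce_features(perm)
  expect_setequal(names(redp), names(red))
  # all features dropped -> advisory error
  expect_error(reduce_features(tibble::tibble(a = rep(1, 10), b = rep(2, 10))),
               "relax")
})

test_that("supervised selection keeps the class-separating features", {
  tbl <- withr::with_seed(8, {
    out <- tibble::as_tibble(as.data.frame(matrix(rnorm(60 * 10), 60)))
    names(out) <- sprintf("f%02d", 1:10)
    out$f01 <- out$f01 + rep(c(0, 4), each = 30)  # strong class signal
    out$f02 <- out$f02 + rep(c(0, 2), each = 30)  # weaker signal
    out
  })
  labels <- rep(c("neg", "pos"), each = 30)
  sel <- select_discriminative(tbl, labels, n_keep = 2)
  expect_setequal(setdiff(names(sel$matrix), "image_id"), c("f01", "f02"))
  expect_equal(nrow(sel$scores), 10L)
  expect_error(select_discriminative(tbl, rep("x", 60)), "two levels")
})
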