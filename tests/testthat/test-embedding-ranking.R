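test_that("dunn_index matches hand-worked cases and sentinel policies", {
  expect_equal(dunn_index(rbind(c(0, 0), c(0, 1)), rbind(c(10, 0), c(10, 1))),
               10)
  expect_equal(dunn_index(rbind(c(0, 0), c(1, 1)), rbind(c(1, 1), c(4, 4))),
               0)   # shared point: zero separation
  expect_equal(dunn_index(rbind(c(0, 0)), rbind(c(1, 0))), Inf)
  expect_error(dunn_index(matrix(numeric(0), 0, 2), rbind(c(0, 0))),
               "nonempty")
})

test_that("dunn_index agrees exactly with the brute-force oracle on random instances", {
  withr::with_seed(123, {
    for (trial in 1:200) {
      na <- sample(1:50, 1); nb <- sample(1:50, 1)
      a <- matrix(rnorm(na * 2), na)
      b <- matrix(rnorm(nb * 2), nb)
      expect_equal(dunn_index(a, b), brute_dunn(a, b), tolerance = 1e-12)
    }
  })
})

test_that("dunn_index is scale invariant and label symmetric", {
  withr::with_seed(77, {
    for (i in 1:20) {
      a <- matrix(rnorm(16), 8)
      b <- matrix(rnorm(16, mean = 2), 8)
      d <- dunn_index(a, b)
      expect_equal(dunn_index(b, a), d)
      for (s in c(0.01, 3, 1e4)) {
        expect_equal(dunn_index(a * s, b * s), d, tolerance = 1e-9)
      }
    }
  })
})

test_that("t-SNE embedding is deterministic and separates distinct clouds", {
  sim <- simulate_feature_screen(n_probes = 5, shifted = character(), seed = 2)
  e1 <- embed_tsne(sim$features, seed = 0)
  e2 <- embed_tsne(sim$features, seed = 0)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), nrow(sim$features))
  expect_true(all(is.finite(e1$x)), all(is.finite(e1$y)))

  expect_error(embed_tsne(sim$features[1:3, ]), "at least 5")

  # two well-separated Gaussian clouds embed with high silhouette
  sils <- sapply(1:5, function(s) {
    withr::with_seed(s, {
      X <- rbind(matrix(rnorm(40 * 10), 40),
                 matrix(rnorm(40 * 10, mean = 4), 40))
      tbl <- tibble::as_tibble(as.data.frame(X))
      tbl$image_id <- sprintf("i%02d", 1:80)
      emb <- embed_tsne(tbl, seed = s)
      mean(cluster::silhouette(rep(1:2, each = 40),
                               dist(cbind(emb$x, emb$y)))[, 3])
    })
  })
  expect_gt(median(sils), 0.5)
})

test_that("a strongly shifted probe is ranked first and ranking is well-formed", {
  hits <- sapply(1:20, function(s) {
    sim <- simulate_feature_screen(n_probes = 8, shifted = "D3922",
                                   shift = 10, seed = s)
    emb <- embed_tsne(sim$features, seed = s)
    rk <- rank_probes(emb, sim$layout)
    expect_setequal(rk$rank, seq_len(nrow(rk)))   # ranks are a permutation
    expect_true(all(diff(rk$dunn_index) <= 0))    # sorted descending
    rk$probe_sku[rk$rank == 1]
  })
  expect_gte(mean(hits == "D3922"), 0.9)
})

test_that("null screens produce exchangeable Dunn ranks across probes", {
  ranks <- lapply(1:8, function(s) {
    sim <- simulate_feature_screen(n_probes = 6, shifted = character(),
                                   seed = 100 + s)
    emb <- embed_tsne(sim$features, seed = s)
    rk <- rank_probes(emb, sim$layout)
    rk[order(rk$probe_sku), c("probe_sku", "rank")]
  })
  pooled <- dplyr::bind_rows(ranks)
  kw <- stats::kruskal.test(pooled$rank, factor(pooled$probe_sku))
  expect_gt(kw$p.value, 0.01)
})

test_that("relabelling KO and WT leaves the Dunn index unchanged", {
  sim <- simulate_feature_screen(n_probes = 4, shifted = "D3922", seed = 9)
  emb <- embed_tsne(sim$features, seed = 0)
  rk1 <- rank_probes(emb, sim$layout)
  flipped <- sim$layout
  flipped$condition <- ifelse(flipped$condition == "KO", "WT", "KO")
  rk2 <- rank_probes(emb, flipped)
  expect_equal(rk1$dunn_index[order(rk1$probe_sku)],
               rk2$dunn_index[order(rk2$probe_sku)])
})

test_that("probes missing a condition are excluded with a warning", {
  sim <- simulate_feature_screen(n_probes = 3, seed = 4)
  emb <- embed_tsne(sim$features, seed = 0)
  cut <- sim$layout[!(sim$layout$probe_sku == "D3922" &
                        sim$layout$condition == "KO"), ]
  class(cut) <- class(tibble::tibble())
  expect_warning(rk <- rank_probes(emb, cut), "D3922")
  expect_false("D3922" %in% rk$probe_sku)
})

test_that("fold-change analysis embeds both arms jointly and honours sentinels", {
  # identical arms (duplicated rows) -> fold change exactly 1 everywhere
  sim <- simulate_feature_screen(n_probes = 4, shifted = "D3922", shift = 5,
                                 treatments = c("DMSO", "mTORi"),
                                 shift_by_treatment = list(DMSO = 5, mTORi = 5),
                                 seed = 11)
  feats <- sim$features
  arm <- sim$layout$treatment[match(feats$image_id, sim$layout$image_id)]
  base <- feats[arm == "DMSO", setdiff(names(feats), "image_id")]
  copied <- dplyr::bind_rows(base, base)
  copied$image_id <- feats$image_id
  fc0 <- fold_change_ranking(copied, sim$layout)
  expect_true(all(fc0$fold_change == 1))

  # a baseline hit whose KO shift triples under treatment attains the top
  # fold change among baseline-ranked probes (the usual workflow computes
  # fold changes only for the top control-arm probes)
  top <- sapply(1:20, function(s) {
    sim <- simulate_feature_screen(
      n_probes = 6, shifted = "D3922", treatments = c("DMSO", "mTORi"),
      shift_by_treatment = list(DMSO = 3, mTORi = 9), seed = 200 + s)
    fc <- fold_change_ranking(sim$features, sim$layout, top_n = 3,
                              perplexity = 12, seed = s)
    fc$probe_sku[which.max(fc$fold_change)]
  })
  expect_gte(mean(top == "D3922"), 0.8)
})

test_that("null treatment arms give fold changes distributed around 1", {
  meds <- sapply(1:8, function(s) {
    sim <- simulate_feature_screen(
      n_probes = 5, shifted = "D3922", treatments = c("DMSO", "mTORi"),
      shift_by_treatment = list(DMSO = 4, mTORi = 4), seed = 300 + s)
    fc <- fold_change_ranking(sim$features, sim$layout, perplexity = 12,
                              seed = s)
    median(fc$fold_change[is.finite(fc$fold_change)])
  })
  expect_gte(median(meds), 0.5)
  expect_lte(median(meds), 2)
})

test_that("tidy, glance and autoplot work on results", {
  sim <- simulate_feature_screen(n_probes = 4, shifted = "D3922", seed = 6)
  emb <- embed_tsne(sim$features, seed = 0)
  rk <- rank_probes(emb, sim$layout)
  td <- generics::tidy(rk)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "phenoprobe_ranking"))
  gl <- generics::glance(rk)
  expect_equal(gl$n_probes, 4L)
  expect_s3_class(ggplot2::autoplot(rk), "ggplot")
  expect_s3_class(ggplot2::autoplot(emb, layout = sim$layout), "ggplot")
  expect_s3_class(plot_probe_embedding(emb, sim$layout, "D3922"), "ggplot")
})

test_that("a probe's median Dunn index is non-decreasing in its effect size", {
  med_dunn <- sapply(c(2, 5, 10), function(sh) {
    median(sapply(1:20, function(s) {
      sim <- simulate_feature_screen(n_probes = 5, shifted = "D3922",
                                     shift = sh, seed = 400 + s)
      emb <- embed_tsne(sim$features, seed = s)
      rk <- rank_probes(emb, sim$layout)
      rk$dunn_index[rk$probe_sku == "D3922"]
    }))
  })
  expect_true(all(diff(med_dunn) >= 0))
})
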