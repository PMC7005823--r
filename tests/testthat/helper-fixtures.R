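# Shared fixtures built in code at test time.

rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]

tiny_layout <- function(n_probes = 2, skus = c("D3922", "N1148")) {
  skus <- skus[seq_len(n_probes)]
  grid <- tidyr::expand_grid(probe_sku = skus, condition = c("KO", "WT"),
                             replicate = 1:2, field = 1:3)
  grid$treatment <- "DMSO"
  grid$image_id <- sprintf("%s_%s_r%d_f%d", grid$probe_sku, grid$condition,
                           grid$replicate, grid$field)
  grid$path <- paste0(grid$image_id, ".tif")
  validate_layout(grid)
}

# feature-level screen simulator: per-probe Gaussian feature clouds with a
# KO-side mean shift for selected probes; exercises embedding/ranking
# without image rendering
simulate_feature_screen <- function(n_probes = 10, images_per_arm = 6,
                                    shifted = character(), shift = 5,
                                    n_feat = 20, treatments = "DMSO",
                                    shift_by_treatment = NULL, seed = 1) {
  withr::with_seed(seed, {
    skus <- panel_manifest()$sku[seq_len(n_probes)]
    rows <- list(); meta <- list()
    centres <- lapply(stats::setNames(skus, skus),
                      function(sku) rnorm(n_feat, sd = 2))  # probe identity,
    # shared across treatment arms as in a real screen
    for (trt in treatments) {
      for (sku in skus) {
        centre <- centres[[sku]]
        for (cond in c("KO", "WT")) {
          eff <- if (sku %in% shifted && cond == "KO") {
            s <- if (!is.null(shift_by_treatment)) shift_by_treatment[[trt]] else shift
            # a phenotype shift moves many correlated features at once, as
            # image-derived feature banks do; spread it over half the columns
            c(rep(s / sqrt(10), 10), rep(0, n_feat - 10))
          } else rep(0, n_feat)
          for (i in seq_len(images_per_arm)) {
            rows[[length(rows) + 1L]] <- centre + eff + rnorm(n_feat)
            meta[[length(meta) + 1L]] <- data.frame(
              probe_sku = sku, condition = cond, treatment = trt,
              replicate = (i - 1L) %/% 3L + 1L, field = (i - 1L) %% 3L + 1L,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    feats <- as.data.frame(do.call(rbind, rows))
    names(feats) <- sprintf("f%02d", seq_len(n_feat))
    layout <- do.call(rbind, meta)
    layout$image_id <- sprintf("img%04d", seq_len(nrow(layout)))
    layout$path <- paste0(layout$image_id, ".tif")
    feats$image_id <- layout$image_id
    list(features = tibble::as_tibble(feats),
         layout = validate_layout(layout))
  })
}

brute_dunn <- function(a, b) {
  # independent all-pairs oracle
  cross <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    cross <- min(cross, sqrt(sum((a[i, ] - b[j, ])^2)))
  }
  diam <- function(m) {
    d <- 0
    if (nrow(m) > 1) {
      for (i in 1:(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
        d <- max(d, sqrt(sum((m[i, ] - m[j, ])^2)))
      }
    }
    d
  }
  if (cross == 0) return(0)
  dd <- max(diam(a), diam(b))
  if (dd == 0) return(Inf)
  cross / dd
}
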