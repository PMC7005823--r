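# phenoprobe

Phenotype profiling for fluorescent-probe imaging screens.

## What problem this solves

A probe-panel screen images a panel of fluorescent chemical probes — each
reporting on a defined cellular process — across two experimental
conditions, typically a gene knockout (KO) against wild type (WT), with a
handful of fields per probe per condition. The probes whose staining differs
between conditions point directly at the cellular processes the perturbed
gene touches. Because those differences range from punctate accumulation to
subtle redistribution, segmentation-based quantification (which must be told
what to measure) misses or invents hits; this package ranks probes with a
segmentation-free, whole-image approach and ships the segmentation-based
comparator so both can be run on the same screen.

The pipeline:

* **Feature bank** — each probe-channel image is mapped to a fixed bank of
  **923 whole-image morphological features**: statistical, histogram,
  Haralick/Tamura texture, moment, Zernike, Gabor, Radon and Chebyshev
  families computed over a stack of image transforms (raw, Fourier, wavelet,
  Chebyshev reconstruction, edge).
* **Reduction** — variance, pairwise-correlation and collinearity (VIF)
  filters with full per-column provenance.
* **Embedding** — exact t-SNE of the whole screen into 2D, deterministic
  for a fixed seed.
* **Ranking** — per probe, the **Dunn index** between its KO and WT points
  in the shared embedding,

  Dunn = min inter-cluster distance / max within-cluster diameter,

  ranked descending: a high Dunn means the probe separates the two
  conditions cleanly.
* **Treatment mode** — two treatment arms embedded jointly and compared as
  per-probe Dunn fold changes.
* **Synthetic screens** — `generate_screen()` renders complete two-channel
  TIFF screens (nuclei + probe channel; diffuse / punctate / nuclear /
  unstained-with-artifacts phenotypes) with ground truth, so the whole
  pipeline is testable without instrument data.

The comparator pipeline segments nuclei in the DNA channel, approximates
cells by distance-N expansion, and takes **237 per-object measurements**
(granularity, neighbours, intensity, radial distribution, texture),
aggregated to per-image means and fed through the identical downstream
stages.

## Worked example

```r
library(phenoprobe)

# a complete synthetic screen: 44 probes x 12 images, 8 true positives
screen <- generate_screen(screen_config(seed = 1), write_images = FALSE)
nrow(screen$layout)
#> [1] 528

# full pipeline: 923 features -> reduction -> t-SNE -> Dunn ranking
res <- profile_screen(screen$layout, mode = "charm", seed = 0)
glance(res)
#> # A tibble: 1 x 9
#>   mode  n_images n_features n_retained n_probes top_probe max_dunn median_dunn
#>   <chr>    <int>      <int>      <int>    <int> <chr>        <dbl>       <dbl>
#> 1 charm      528        923        229       44 N3786         2.27      0.0734
#> # i 1 more variable: n_infinite <int>

# where do the 8 ground-truth positives land?
tp <- screen$truth$probe_sku[screen$truth$is_true_positive]
sort(tidy(res)$rank[tidy(res)$probe_sku %in% tp])
#> [1] 1 2 3 4 5 6 7 8
```

All eight probes that truly differ between KO and WT occupy the top eight
ranks; `n_retained` is the data-dependent number of features surviving
reduction. `autoplot(res$ranking, top = 15)` draws the ranking bar chart,
`autoplot(res$embedding, layout = screen$layout)` the embedding, and
`plot_probe_embedding(res$embedding, screen$layout, tp[1:4])` the per-probe
zoom panels. For screens written to disk, `load_plate_map()` +
`extract_features()` replace the in-memory layout, and a thin command-line
front end with `simulate` / `extract` / `reduce` / `rank` / `compare`
subcommands lives in `inst/cli/phenoprobe.R`.

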