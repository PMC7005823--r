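---
title: "Methods: probe-panel phenotype profiling with whole-image features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe-panel phenotype profiling with whole-image features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phenoprobe)
```

## The problem this package addresses

A probe-panel imaging screen exposes two cell populations — typically a gene
knockout (KO) and its parental wild type (WT) — to a panel of fluorescent
chemical probes, one probe per well, and images every well. Each probe
reports on a defined cellular process (neutral lipid storage, sterol
trafficking, ion concentrations, organelle morphology, ...), so the set of
probes whose staining pattern *differs* between KO and WT is a direct,
interpretable readout of which processes the knocked-out gene touches.

The analysis question is: *given a few images per probe per condition, which
probes separate the two conditions?* The catch is that the interesting
phenotypes are heterogeneous — puncta appearing, stains redistributing,
intensity shifting — and segmentation-based quantification requires knowing
in advance what to measure. This package instead ranks probes with a
segmentation-free pipeline:

1. **Whole-image features.** Every probe-channel image is mapped to a fixed
   bank of 923 named morphological features (`extract_charm()`).
2. **Feature reduction.** Low-variance, highly correlated and collinear
   columns are removed (`reduce_features()`).
3. **Embedding.** All images of the screen are embedded together into 2D
   with t-SNE (`embed_tsne()`).
4. **Scoring.** For each probe, the Dunn index between its KO and WT points
   in the shared embedding measures how cleanly the two conditions separate;
   probes are ranked by this score (`rank_probes()`).

A segmentation-based comparator (nuclei detection, fixed-distance cell
approximation, 237 per-object measurements) is included so the two
philosophies can be compared on the same screens, and a treatment mode
compares Dunn indices across two treatment arms as a fold change
(`fold_change_ranking()`).

## The feature bank

The 923 features form a fixed (transform plane × feature family) grid; the
manifest (`charm_manifest()`) is generated in code and is identical on every
platform. The transform stack comprises the raw image, the shifted
log-magnitude Fourier spectrum, a single-level Haar wavelet approximation
and combined detail magnitude, an order-20 Chebyshev polynomial
reconstruction, a Sobel edge-magnitude plane, and the spectrum of the
wavelet approximation. Five statistical families (pixel statistics,
multiscale histograms, direction-averaged Haralick texture, Tamura texture,
central/Hu moments) run on all seven planes; Radon projection statistics,
Chebyshev coefficient histograms, Chebyshev–Fourier histograms, Zernike
moment magnitudes, a 7-kernel Gabor bank, edge statistics and Otsu object
statistics run on documented subsets. The widths were fixed once, when the
grid was designed, so that the total is exactly 923; the grid — not any
published feature list — is the source of truth, because downstream stages
depend only on the count and on family semantics.

Numerical conventions, chosen for determinism and boundedness:

* every plane is contrast-stretched to [0, 1]; a constant plane maps to
  zeros;
* co-occurrence texture uses 32 gray levels on the stretched plane, a
  symmetric GLCM, and four directions whose feature means/ranges make the
  family exactly invariant under 90° grid rotations;
* Zernike magnitudes (orders ≤ 8) are computed on the centred inscribed
  disk, making them rotation-invariant as well (both invariances are tested
  at tolerance 1e-6);
* degenerate statistics (correlation of a constant GLCM, skewness of a
  constant plane, ...) are imputed as 0 so every extraction is finite —
  feature reduction and t-SNE require finite input;
* Sobel gradients use circular boundary conditions, which commute with
  exact grid rotations.

Whole-image features are deliberately translation-*sensitive* (there is no
per-cell alignment); this is inherent to the segmentation-free philosophy
and is documented rather than "fixed".

## The segmentation comparator

Nuclei are detected in the DNA channel by Gaussian smoothing (σ = 2 px),
Otsu thresholding, hole filling and 20-px minimum-area filtering, with no
declumping (synthetic nuclei are non-overlapping by construction; merged
real nuclei would stay merged). Cell regions are approximated by expanding
each nucleus up to N = 10 px outward, assigning contested pixels to the
nearest nucleus in exact Euclidean distance with ties to the lower label —
implemented with integer squared distances so the partition property
(disjoint regions, each containing its nucleus) is exact and is tested
against a brute-force per-pixel oracle.

The 237 per-object measurements split into granularity (16-scale morphological
opening spectrum), neighbourhood (8), intensity (33), nucleus-centred radial
intensity distribution (8 bins × 3 statistics) and within-object
direction-averaged co-occurrence texture (13 features × mean/range × 6
scales). As with the whole-image bank, the grid widths were fixed by design
to total exactly 237. Per-object rows are aggregated to per-image means;
an image with zero detected objects yields an all-NA row flagged as empty,
and such rows are dropped (with a message) at embedding time — NA rows
would poison both the correlation filter and t-SNE.

## Feature reduction

Three ordered passes, cheapest first: variance (drop column variance
< 1e-8), greedy correlation (drop a column whose |Pearson r| with any
earlier retained column exceeds 0.95 — manifest order makes the result
deterministic), and iterative collinearity (drop the largest
variance-inflation-factor column until all VIF ≤ 10). VIF is computed as the
diagonal of the inverse correlation matrix with a 1e-8 ridge so exactly
collinear groups stay finite; a single remaining column has VIF 1 by
convention. The pipeline records per-column drop reasons
(`reduction_provenance()`), is idempotent, and conserves columns (retained +
dropped = input). The thresholds are conventional defaults, not calibrated
to reproduce any particular retained-feature count: the retained count is
data-dependent by nature.

An optional discriminative-selection stage (`select_discriminative()`,
Welch-t ranking of features against two labelled image classes) exists for
designs with control wells but is deliberately not part of
`reduce_features()`: a KO-vs-WT probe screen has no per-probe
positive/negative control classes, so the default pipeline is label-free.

## Embedding and Dunn scoring

t-SNE is computed exactly (no Barnes–Hut approximation) with perplexity 30
clipped to (n−1)/3, 750 gradient iterations, early exaggeration 12 for the
first 250, learning rate 200, and deterministic PCA initialisation with
sign-fixed loadings — identical input gives identical output, which the
tests rely on. No t-SNE package is declared as a dependency; the
implementation lives in the package and is validated behaviourally
(well-separated Gaussian clouds must embed with median silhouette > 0.5
against the true labels, scored by `cluster::silhouette`). Features are
z-scored before embedding and inputs wider than 50 columns are first
projected to 50 principal components.

The Dunn index for a probe uses its KO points as one cluster and its WT
points as the other, both taken from the **single global embedding** of the
whole screen — per-probe re-embedding would make scores incomparable across
probes. Dunn = (minimum KO–WT cross distance) / (largest within-cluster
diameter). Sentinels for 12-point clusters that can degenerate: zero
separation gives 0; zero diameters with positive separation give +Inf
(serialised as the token `"inf"` in CSV). Ranking ties are broken by
ascending SKU for determinism. A reduced-feature-space Dunn option is not
provided beyond the embedding because t-SNE coordinates are the package's
declared scoring space; users can call `dunn_index()` directly on any
coordinate matrix for robustness checks.

For treatment fold changes, both arms are embedded **jointly** in one t-SNE:
separate embeddings have arbitrary relative scales, which would make the
ratio dunn(treated)/dunn(control) meaningless. Sentinels: control 0 with
treated positive → +Inf; both 0 (or both +Inf) → 1.

## The synthetic screen generator

No instrument images ship with the package; the generator
(`generate_screen()`) produces the entire study layout with known ground
truth. Defaults encode the modelled screen design: a 44-probe panel, and per
probe and treatment arm 2 conditions × 2 technical replicates × 3 fields
= 12 images; each field is a pair of 16-bit grayscale TIFFs (DNA + probe
channel). Per-image RNG seeds are derived from the master seed by a stable
hash of (probe, condition, treatment, replicate, field), so adding probes to
a configuration never changes existing images.

Phenotype classes and their default parameters:

* **diffuse** — soft cytoplasmic annuli around each nucleus (base intensity
  ~0.25–0.35 on the unit scale);
* **puncta** — diffuse background plus Poisson-many bright soft disks
  (radius 2 px, intensity 0.9) placed in cytoplasmic regions;
* **nuclear** — stain inside nuclei;
* **no_stain** — no probe signal; optionally a faint cytoplasmic
  autofluorescence (0.05) and Poisson-many dim speckle artifacts.

The eight probes with published phenotype identities are the default true
positives: their KO-side spec gains 18 puncta on average (the effect delta);
their WT side and every null probe have identical KO/WT distributions, which
the tests verify at the phenotype-description level. The treatment arm is modelled as a
scalar multiplier on the KO-side delta (default 2 for non-control arms),
encoding a treatment that accentuates the phenotype; the real effect size is
unpublished, so the multiplier is a free parameter of the simulation.

One panel probe (the heavy-metal indicator slot) is configured as an
*artifact confounder*: no stain in either condition, faint autofluorescence
in both, and dim speckle artifacts (2.5–4× the read-noise σ, radius ~2 px)
in the KO arm only. The artifact brightness was chosen to sit just above the
noise ceiling: bright enough that spatially coherent blobs are detectable by
object-level quantification (per-object intensity-tail statistics carry the
strongest KO/WT signal for this probe), dim enough that whole-image
statistics of a contrast-stretched field barely register them. This models
the classic failure mode of segmentation-based analysis — an unstained well
scored as a hit because per-object measurements amplify low-intensity
artifacts. The autofluorescence term exists for the same reason: a perfectly
flat blank field is unrealistic and would make *any* image statistic
hypersensitive to the first coherent structure it meets. The asymmetry this
probe induces between the two pipelines is measurable at the feature level
but modest; at panel scale both pipelines typically rank the probe near the
bottom (the comparison suite in the tests quantifies this).

Noise is Poisson shot noise (photon scale 200) plus Gaussian read noise
(σ = 0.01), clipped to [0, 1]. There is no optical PSF model, no
illumination gradient, no plate or well-edge effects, and no fixed-vs-live
cell permeability modelling: the generator's realism extends exactly as far
as the features can sense (intensity distribution, texture, granularity).
Consequently, passing ranking-recovery tests shows the *pipeline* orders
effect sizes correctly under this generative model; it does not certify
performance on instrument data with artifacts the model omits.

## Problem sizes and default parameters

Parameters that matter, with defaults and units:

| parameter | default | where | meaning |
|---|---|---|---|
| `image_size_px` | 128 | `screen_config()` | field edge length; 64 minimum |
| `cells_per_image` | 12 | `screen_config()` | Poisson mean nuclei per field |
| `nucleus_radius_px` | 6 | `screen_config()` | nucleus radius |
| `noise_sigma` | 0.01 | `screen_config()` | Gaussian read noise (unit scale) |
| `photon_scale` | 200 | `screen_config()` | Poisson photon count scale |
| `effect_puncta_count` | 18 | `screen_config()` | KO-side puncta delta for true positives |
| `n` | 10 px | `expand_cells_distance_n()` | cell-approximation distance |
| `variance_min` | 1e-8 | `reduction_config()` | variance filter |
| `corr_max` | 0.95 | `reduction_config()` | correlation filter |
| `vif_max` | 10 | `reduction_config()` | collinearity filter |
| `perplexity` | 30 | `embed_tsne()` | clipped to (n−1)/3 |

The package's own validation uses deliberately scaled problem sizes: the
full-screen ranking-recovery check runs the complete 44-probe, 528-image
screen at 128 px; multi-seed pipeline-comparison experiments use 8-probe
screens at 96 px over 10 seeds; rotation-invariance and Dunn-oracle suites
use 64–96 px planes and up-to-50-point clusters. These sizes were chosen as
the smallest at which every phenotype class remains legible to the features
(nuclei of radius 6 px with 2.5× cytoplasm need ≳ 90 px fields to hold ~10
cells).

## Known limitations

* t-SNE distances are not metrically faithful; the Dunn index on an
  embedding is a *screening* score, not a calibrated statistic, and no
  p-values are attached to ranks by design.
* With 12 images per probe, single-linkage cross distances and complete
  diameters are noisy; the +Inf/0 sentinels exist precisely because such
  small clusters can degenerate.
* The greedy correlation filter keeps the *first* column of a correlated
  group in manifest order, which is deterministic but not optimal in any
  information-theoretic sense.
* Whole-image features see the whole field: cell-density differences between
  conditions would register as phenotype. In the generator, cell counts are
  drawn identically for both conditions, so this channel is silent in
  validation but real screens should plate conditions at matched density.
* The generator's artifact confounder models one specific failure mode
  (dim coherent speckles); other real-world artifacts (debris, focus drift,
  bubbles) are out of scope.
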