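---
title: "Quantifying tertiary lymphoid structures and stratifying relapse risk from tissue heatmaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tertiary lymphoid structures and stratifying relapse risk from tissue heatmaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlsview)
```

## The problem

Tertiary lymphoid structures (TLS) are ectopic lymphoid aggregates that form
in and around tumours. Their abundance, maturity (aggregate Agg, primary
follicle FL-1, secondary follicle FL-2) and position relative to the tumour
margin carry prognostic information in solid tumours such as stage II
colorectal cancer. `tlsview` implements the computational core of a
heatmap-based TLS risk pipeline: it starts from per-slide tissue label
heatmaps — integer grids in which each cell is one tile classified as
background, normal tissue, tumour or TLS, with a parallel TLS-subtype grid —
and ends at a cross-validated, ensemble-thresholded relapse risk
stratification with attention- and attribution-based explanations.

The package deliberately does **not** segment whole-slide images. Producing
the heatmaps (tile classification, stain handling, encoder training) is
upstream of this package; `tlsview` consumes heatmaps in PNG/TIFF/plain-text
form plus optional per-case patch-feature bags through a pluggable encoder
contract.

## Heatmap post-processing

Isolated mispredicted tiles distort distance and area statistics, so
heatmaps are cleaned before feature construction:

1. normal-tissue pixels are cleared to background;
2. single-pixel components of any tissue class are removed;
3. tumour components smaller than `min_tumor_px` (default 20 pixels) are
   removed;
4. interior holes of the remaining tumour and TLS components are filled
   with the enclosing class.

Components use 8-connectivity; background holes use 4-connectivity (the
standard duality, which prevents a diagonal "leak" from counting as an
escape route). A hole is a background region that cannot reach the grid
border; it takes the majority class of its adjacent non-background pixels,
with ties broken toward tumour, and holes filled as TLS take the majority
subtype of the adjacent TLS pixels (ties toward the more mature stage).
Fill decisions are made against the pre-fill state, so the result does not
depend on hole processing order, and the whole operation is idempotent.

The `ssim()` audit quantifies how much post-processing perturbed a slide:
windowed structural similarity on the label grid treated as an intensity
image (uniform 7x7 window, sample covariance, stabilizing constants
`C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with `L` the maximum label). Values
near 1 indicate the cleaning preserved spatial structure.

```{r ssim-demo}
m <- matrix(0L, 24, 24)
m[6:18, 4:14] <- 2L          # tumour block
m[10, 10] <- 0L              # interior hole
m[3, 20] <- 3L               # stray single-pixel TLS
h <- tissue_heatmap(m)
p <- postprocess(h)
ssim(h, p)
```

## The 226-entry spatial feature registry

Each TLS connected component is summarized by its majority subtype, its
area in mm^2 (pixel count times the squared pixel pitch, default 0.064 mm
per heatmap pixel), and its signed margin distance: the Euclidean distance
from the component centroid to the nearest tumour-boundary pixel, negative
when the centroid lies inside tumour (enclosed pockets count as inside, so
a TLS carved out of the tumour interior is intratumoral). Distances fall
into seven fixed bins (<=0, (0,0.4], (0.4,1.0], (1.0,2.2], (2.2,4.5],
(4.5,6.4], >6.4 mm) and areas into seven fixed bins ((0,0.03],
(0.03,0.05], (0.05,0.07], (0.07,0.10], (0.10,0.15], (0.15,0.28],
>0.28 mm^2).

Counts and areas pool over all slides of a case into a canonical
226-dimensional registry:

* 7 distance bins x 3 subtypes x {count, total area, mean area} = 63;
* 7 area bins x 3 subtypes x {count, total area, mean area} = 63;
* 7 x 7 joint distance-area bins x {count, total area} = 98;
* total tumour area and mean tumour area per slide = 2.

Only the total (226) and the bin structure are externally fixed; the exact
block composition is this package's design, chosen so that the three bin
families triple-book every component (each TLS contributes exactly one
count to each family — a conservation law the test suite enforces) and so
that tumour burden, which the interpretability analysis needs, is present
explicitly. Mean-area entries are 0 when their count is 0, keeping the
vector finite for empty blocks. The registry names and order ship as
machine-readable JSON in `inst/extdata/feature_registry.json`.

## Networks

All networks are trained with a small reverse-mode automatic
differentiation tape written for this package (`R/autodiff.R`); gradients
are verified against central finite differences in the test suite.

**Gated-attention MIL (WSINet).** A case is a bag of patch feature vectors
(width 768 by default). Each instance is embedded by two fully connected
ReLU layers into `f_i`; the attention score is

$$S_i = \mathrm{softmax}_i\big(W(\tanh(W_a f_i) \odot \sigma(W_b f_i))\big),$$

and the case representation is the attention-weighted sum of the `f_i`,
classified by a linear two-class head. The softmax runs over all patches
of a case pooled across its slides.

**SpB.** The standardized 226-vector passes through a 226-128-64-32 ReLU
perceptron to the spatial representation `r_S`. Standardization statistics
are always fitted on training folds only.

**MpB.** Each TLS component is embedded (shipped encoder: a deterministic
shape/subtype descriptor — area, rasterized perimeter, circularity
4&pi;A/P^2, subtype one-hot, signed distance — expanded by a fixed random
projection; any encoder with the same contract can replace it), the
case's embeddings are k-means-clustered into 7 representative centers, and
a gated-attention network pools the centers into `r_M` (width 32). The
fixed 7-row representation gives every case the same shape, which is what
allows batching. Cases with at most 7 (or fewer than 7 distinct)
embeddings use the rows themselves, repeated cyclically; a case with no
TLS gets a zero bag and is flagged.

**MVNet.** With `r_mv = [r_S, r_M]`, four linear maps produce `f_S`,
`f_M`, `f_mvS`, `f_mvM` (width 32 each) and the fusion is

$$f_{fusion} = \big[\,W_{fusion}(f_S \odot f_{mvS}),\;
W_{fusion}(f_M \odot f_{mvM})\,\big].$$

The shared `W_fusion` maps 32 to 16, so `f_fusion` has width 32: it is
simultaneously "twice the `W_fusion` output width" and the 32-wide
penultimate representation consumed by the linear head and by the clinical
fusion — the one reading that satisfies both stated width constraints.

**MMF.** Fourteen encoded clinicopathological covariates pass through four
affine + BatchNorm + ReLU layers (14-64-64-64-32); the clinical embedding
is concatenated with the MVNet penultimate vector into a 64-wide fused
vector and classified by a final linear layer. The whole stack — including
the embedded MVNet — is optimized end-to-end with the final loss; batch
normalization uses batch statistics during training (momentum 0.1) and
frozen running statistics at evaluation, so repeated evaluation calls are
bit-identical.

Hidden widths not externally fixed (attention tower 256/128 for WSINet,
32/16 for MpB) are configuration, recorded in `model_spec()`.

## Training and evaluation protocol

* class-weighted cross-entropy, weights 0.5 (no relapse) and 1.2
  (relapse);
* full-batch Adam at 1e-3; inverse-time learning-rate decay (rate 9e-3)
  for the multi-view models and cosine decay with 10-epoch linear warm-up
  for WSINet and MMF; 500 epochs for prognostic models (100 is the
  convention for treatment-predictive variants); decoupled weight decay
  1e-2 — with full-batch training for hundreds of epochs on a few hundred
  cases, explicit capacity control is what keeps the out-of-fold
  discrimination near the information ceiling rather than memorizing the
  training folds;
* MVNet branches are pretrained separately (default 200 epochs) and the
  fused model fine-tuned end-to-end, and MMF embeds the trained MVNet;
* stratified 5-fold case-level cross-validation: each case is predicted
  exactly once by the model not trained on it, and the same split serves
  every model variant (stratification is this package's choice — plain
  random fifths can produce single-class folds at these cohort sizes);
* for external cohorts the five fold models are averaged first and only
  the ensemble probability is binarized;
* the decision threshold is the Equal-Error-Rate operating point
  (|FPR - FNR| minimized over the unique scores plus +Inf; ties toward
  the smaller threshold; `probability >= t` means high risk). Thresholds
  are dataset-specific by default — recomputed on each evaluated dataset's
  labels, which mirrors per-dataset operating-point selection but does use
  that dataset's labels; `predict(..., threshold = "fixed")` applies the
  development threshold instead.

Evaluation: Mann-Whitney AUROC with tie half-credit and a 2000-replicate
case bootstrap CI, DeLong's structural-components test for paired AUROC
comparison, Kaplan-Meier curves and log-rank tests (via the `survival`
package) for risk-group separation. Cox regression, nomograms and
calibration analyses are intentionally left to standard statistics
tooling; the package exports the per-case table such analyses consume.

## Interpretability

* the top-50 attention tiles per case summarize what the MIL model
  attends to, with ties broken by instance index;
* selected tiles are k-means-clustered into 5 groups for morphological
  review;
* spatial-branch attributions are **exact grouped Shapley values**: the
  226 features are partitioned into at most 12 groups and all `2^g`
  coalitions are enumerated, replacing out-of-coalition groups with
  baseline (cohort-mean) values. Exact enumeration at block granularity
  is deterministic and testable, unlike sampling-based approximations,
  and matches how block-level results are reported. The default 11-group
  partition is one group per distance bin (its distance-subtype block
  plus its joint block), one group per subtype for the area block, and
  the tumour globals. Efficiency (attributions summing to prediction
  minus baseline) holds to 1e-8 by construction and is asserted in tests.
  Negative attribution means protective ("favorable").

## The synthetic cohort generator

`synth_config()` / `make_cohort()` generate the cohorts the test suite
and the worked examples run on. Each slide gets one smoothed tumour blob
(at least 200 px) and a Poisson number of TLS ellipses whose subtype, area
(truncated log-normal) and signed margin distance (uniform over the seven
distance bins, then uniform within a bin sub-range) are sampled from the
configuration; extratumoral components are positioned by bisection along
an outward ray so the realized pixel distance matches the target, and
intratumoral components are carved into the tumour interior. Single-pixel
and sub-threshold noise components are sprinkled in so post-processing has
real work to do. The generator emits per-component ground truth, and the
suite checks that the extraction pipeline recovers planted extratumoral
distances within one pixel pitch.

Outcomes follow a planted mechanism: with `z` denoting cohort
standardization,

$$\eta = \beta\, z(\text{FL-2 area in the } (1.0,2.2] \text{ and }
(2.2,4.5] \text{ mm bands}) - \beta_T\, z(\text{tumour area})
+ \beta_c\, z(\text{clinical score}),$$

relapse labels are Bernoulli with probability
`plogis(-link_scale * eta)`, and relapse-free times are exponential with
hazard proportional to `exp(-eta)`, censored uniformly before the event
for a configured fraction of cases. Defaults: `beta = 2`,
`beta_tumor = 1`, `beta_clin = 0.5`, `link_scale = 2`. The link scale is
a calibration constant: with it, the true linear predictor discriminates
relapse with AUROC around 0.94 (so a planted effect of `beta = 2` is a
genuinely strong signal, recoverable to at least 0.85 by the image-only
models), while `beta = 0` leaves the planted feature at chance. Patch
bags are two-component Gaussian mixtures whose signal fraction rises
monotonically with the case's risk latent, so attention has something to
find.

What the generator does **not** emulate: multi-focal tumours (single blob
per slide by default), irregular TLS shapes beyond ellipses, spatially
correlated misclassification noise, informative censoring, covariate
shift between cohorts, or any real histology appearance. Passing the
planted-recovery suite therefore demonstrates that the pipeline's
machinery is correct and self-consistent — not that the headline
discrimination would transfer to real slides, which requires external
cohorts and trained tile encoders upstream of this package.

## Numerical choices and degenerate inputs

* label grids are validated (`labels` in 0..3, subtypes nonzero exactly on
  TLS pixels, positive pixel pitch);
* `signed_margin_distance` errors on slides without tumour; the centroid's
  nearest integer pixel (half-up rounding, clamped to the grid) decides
  the sign;
* k-means uses k-means++ seeding under an explicit recorded seed, Lloyd
  iterations capped at 300, and up to 5 reseeded restarts if an empty
  cluster aborts a run; `cluster_patches` reduces k with a warning when
  fewer tiles than clusters are given;
* the EER sweep declares degeneracy (with a warning) when all scores are
  equal; DeLong errors on degenerate variance unless the two score
  vectors are identical (z = 0, p = 1);
* cross-entropy probabilities are clipped at 1e-12 with a warning;
* every stochastic step (fold split, initialization, clustering,
  generation, bootstrap) takes an explicit seed, and training itself is
  RNG-free (full batch, no dropout), which is what makes the leakage and
  rerun-determinism tests exact.

## Problem sizes used by the shipped checks

The planted-recovery suite runs a 300-case cohort (three 176 x 176 slides
per case, `beta = 2`, seed pinned), trains MVNet and the SpB-only variant
under the full 500-epoch protocol, and compares against a 300-case null
cohort with the image-linked effects removed. Unit and property tests use
cohorts of 10-25 cases and grids of 16-60 pixels, sized so the whole
suite completes in a few minutes on one CPU. These sizes are the package's
validation design; nothing in the method depends on them.

## Known limitations

* The shipped TLS encoder is a fixed geometric descriptor, not a learned
  morphology model; it exercises the MpB contract and provides subtype
  separation, but real deployments should plug in a trained encoder.
* Dataset-specific EER thresholds use the evaluated dataset's labels;
  when truly prospective operation is needed, use the fixed development
  threshold and expect the documented sensitivity trade-off.
* Exact grouped Shapley is limited to 12 groups (4096 coalition
  evaluations); finer-grained attribution requires a different estimator.
* The post-processing hole-fill decides ties toward tumour; heatmaps in
  which large cavities are genuinely background (e.g. lumen) would need
  the fill disabled.
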