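# tlsview

Tertiary lymphoid structures (TLS) — ectopic lymphoid aggregates graded by
maturity as Agg (aggregate), FL-1 (primary follicle) and FL-2 (secondary
follicle) — are a prognostic feature of the tumour microenvironment in
solid tumours such as stage II colorectal cancer. `tlsview` is for
computational pathology researchers who already have per-slide **tissue
label heatmaps** (tile-level background / normal / tumour / TLS maps with
a TLS-subtype channel, e.g. from an upstream segmentation model) and want
to turn them into a validated, explainable relapse-risk stratification.

The package implements, end to end:

* **Heatmap post-processing** — normal-tissue removal, single-pixel and
  sub-threshold (default 20 px) tumour component removal, interior hole
  filling — with a windowed SSIM audit of structural preservation;
* **The 226-entry spatial feature registry.** Each TLS component gets a
  subtype, an area (mm²) and a signed margin distance: the Euclidean
  distance from its centroid to the nearest tumour-boundary pixel,
  negative inside tumour. Distances bin into
  ≤0, (0,0.4], (0.4,1.0], (1.0,2.2], (2.2,4.5], (4.5,6.4], >6.4 mm and
  areas into (0,0.03], (0.03,0.05], (0.05,0.07], (0.07,0.10],
  (0.10,0.15], (0.15,0.28], >0.28 mm²; counts, total and mean areas per
  distance × subtype, area × subtype and joint distance × area bin plus
  tumour globals give exactly 226 case-level features;
* **Gated-attention multiple-instance learning**: per-instance scores
  S_i = softmax_i(W(tanh(W_a f_i) ⊙ σ(W_b f_i))) pooling patch bags
  (WSINet) and per-case morphological cluster centers (MpB, 7 k-means
  centers per case);
* **Multi-view fusion (MVNet)**
  f_fusion = [W_fusion(f_S ⊙ f_mvS), W_fusion(f_M ⊙ f_mvM)] joining the
  spatial MLP branch and the morphological attention branch, and
  **multimodal fusion (MMF)** concatenating a 32-d clinical embedding
  (14 covariates through four BatchNorm/ReLU layers) with the 32-d MVNet
  penultimate vector;
* **The training/evaluation protocol**: class-weighted cross-entropy
  (0.5 / 1.2), full-batch Adam with inverse-time or warm-up-cosine decay,
  stratified 5-fold case-level cross-validation, ensemble averaging
  before binarization, Equal-Error-Rate thresholding, AUROC with
  bootstrap CIs, DeLong comparisons, Kaplan–Meier / log-rank survival
  separation;
* **Interpretability**: top-50 attention tiles, 5-cluster patch
  summaries, and exact grouped Shapley attribution over the spatial
  registry (full coalition enumeration over ≤12 feature groups);
* **A synthetic cohort generator** that plants TLS with known subtype,
  area and margin distance, relapse outcomes driven by peritumoral FL-2
  burden, and patch bags with a recoverable attention signal — the
  ground truth every test in the package is checked against.

All networks run on a small reverse-mode autodiff engine included in the
package; gradients are verified against finite differences in the test
suite.

## Worked example

```r
library(tlsview)

cfg    <- synth_config(n_cases = 60, seed = 7)   # synthetic study cohort
cohort <- make_cohort(cfg, keep_heatmaps = FALSE)
fit    <- fit_risk_model(cohort, model = "mvnet", seed = 1)
print(fit)
```

```
TLS risk model (mvnet), 5-fold CV, seed 1
  cases: 60 (35 relapse)
  out-of-fold AUROC: 0.693 (95% CI 0.552-0.825)
  EER threshold: 0.7926 (FPR 0.360, FNR 0.343)
  log-rank (high vs low risk): chi-sq 5.73, p 1.67e-02
```

Every case was predicted once by the fold model not trained on it; the
AUROC is the out-of-fold discrimination of relapse (at n = 60 the planted
signal is only partly recoverable — at the package's reference scale of
300 cases the same protocol reaches ≈ 0.86), the threshold is the
operating point where false-positive and false-negative rates meet, and
the log-rank line shows that the resulting high/low risk groups separate
in relapse-free survival. `predict(fit, new_cohort)` applies the
five-model ensemble to another cohort; `plot(fit)` draws the Kaplan–Meier
curves.

Attribution for one case:

```r
f <- make_spatial_predictor(fit, cohort)
shapley_spb(f, cohort$spatial[1, ], colMeans(cohort$spatial))
```

```
grouped Shapley attribution: prediction 0.9938, baseline 0.5925
        group    value   direction
1  dist_10_22  0.18434 unfavorable
2  dist_22_45  0.08990 unfavorable
3       tumor  0.06197 unfavorable
...
```

This case's ensemble relapse probability (0.99) sits far above the
cohort-mean baseline (0.59) mostly because it carries *less* peritumoral
FL-2 mass in the 1.0–2.2 and 2.2–4.5 mm bands than average (positive =
risk-increasing attribution) plus an above-average tumour burden — the
planted mechanism of the synthetic cohort, recovered from the fitted
model alone.

A thin command-line front end ships in `inst/cli/tlsview.R`
(`synth`, `heatmap`, `features`, `run-all`).

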