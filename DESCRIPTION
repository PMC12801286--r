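Package: tlsview
Title: Tertiary Lymphoid Structure Quantification and Multi-View Survival
    Risk Stratification from Tissue Heatmaps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tertiary lymphoid structures (TLS) from per-slide
    tissue label heatmaps and stratifies relapse risk in solid tumours.
    Provides heatmap post-processing with a structural-similarity audit,
    a 226-dimensional spatial feature registry built from TLS subtype,
    area and signed tumor-margin distance bins, gated-attention
    multiple-instance learning, a two-branch multi-view fusion network
    with optional clinical multimodal fusion, a stratified
    cross-validation and ensemble protocol with Equal-Error-Rate
    thresholding, survival evaluation (AUROC, DeLong, Kaplan-Meier,
    log-rank), exact grouped Shapley attribution, and a seed-reproducible
    synthetic cohort generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    EBImage,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
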