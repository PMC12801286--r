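small_cfg <- function(tls_mean = 4, ...)
  synth_config(n_cases = 10, tls_mean = tls_mean, seed = 77, ...)

test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- small_cfg()
  c1 <- suppressWarnings(make_cohort(cfg, keep_heatmaps = FALSE))
  c2 <- suppressWarnings(make_cohort(cfg, keep_heatmaps = FALSE))
  expect_identical(c1$spatial, c2$spatial)
  expect_identical(c1$cases, c2$cases)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(lapply(c1$morph, `[[`, "centers"),
                   lapply(c2$morph, `[[`, "centers"))
  expect_identical(c1$bags, c2$bags)
  c3 <- suppressWarnings(
    make_cohort(synth_config(n_cases = 10, tls_mean = 4, seed = 78),
                keep_heatmaps = FALSE))
  expect_false(identical(c1$spatial, c3$spatial))
})

test_that("planted component areas follow pixel-area arithmetic", {
  m <- matrix(0L, 40, 40)
  m[5:16, 5:16] <- 3L            # 12 x 12 block
  s <- matrix(0L, 40, 40); s[m == 3L] <- 2L
  h <- tissue_heatmap(m, s, pixel_pitch_mm = 0.064)
  comp <- find_components(h, "tls")[[1]]
  expect_equal(comp$area_mm2, 0.589824)
})

test_that("a zero-TLS configuration yields tumor-only heatmaps", {
  cfg <- small_cfg(tls_mean = 0, noise_singletons = 0)
  set.seed(5)
  out <- make_heatmap(cfg, slide_id = "s")
  expect_equal(nrow(out$truth), 0L)
  expect_true(sum(out$heatmap$labels == 2L) >= 200L)
  expect_equal(sum(out$heatmap$labels == 3L), 0L)
})

test_that("the pipeline recovers planted extratumoral distances within one pixel", {
  cfg <- small_cfg()
  set.seed(91)
  checked <- 0L
  for (bin in 2:7) {
    for (rep in 1:4) {
      plan <- data.frame(
        subtype = sample(3L, 1L),
        area_mm2 = runif(1, 0.02, 0.12),
        target_dist_mm = runif(1, cfg$dist_bin_ranges[bin, 1] + 0.07,
                               cfg$dist_bin_ranges[bin, 2] - 0.07),
        dist_bin = bin - 1L)
      out <- make_heatmap(cfg, plan = plan, slide_id = "s")
      if (nrow(out$truth) == 0L) next
      h <- postprocess(out$heatmap)
      comps <- tls_components(h)
      expect_length(comps, 1L)
      expect_lt(abs(comps[[1]]$signed_margin_distance_mm -
                      plan$target_dist_mm),
                cfg$pixel_pitch_mm * (1 + 1e-9))
      expect_equal(as.integer(comps[[1]]$subtype), plan$subtype)
      expect_equal(bin_distance(comps[[1]]$signed_margin_distance_mm),
                   plan$dist_bin)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 18L)   # placements rarely fail
})

test_that("intratumoral plants land in the at-or-inside-margin bin", {
  cfg <- small_cfg()
  set.seed(93)
  hits <- 0L
  for (rep in 1:6) {
    plan <- data.frame(subtype = 3L, area_mm2 = 0.04,
                       target_dist_mm = runif(1, -1, -0.2), dist_bin = 0L)
    out <- make_heatmap(cfg, plan = plan, slide_id = "s")
    if (nrow(out$truth) == 0L) next
    h <- postprocess(out$heatmap)
    comps <- tls_components(h)
    expect_length(comps, 1L)
    expect_lte(comps[[1]]$signed_margin_distance_mm, 0)
    expect_equal(bin_distance(comps[[1]]$signed_margin_distance_mm), 0L)
    hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("sampled TLS attributes match their configured distributions", {
  cfg <- synth_config(n_cases = 10, seed = 1)
  set.seed(97)
  plan <- sample_component_plan(cfg, 2000L)
  # areas: truncated log-normal CDF
  lo <- plnorm(cfg$area_trunc[1], cfg$area_meanlog, cfg$area_sdlog)
  hi <- plnorm(cfg$area_trunc[2], cfg$area_meanlog, cfg$area_sdlog)
  cdf_area <- function(x) (plnorm(x, cfg$area_meanlog, cfg$area_sdlog) - lo) /
    (hi - lo)
  expect_gt(ks.test(plan$area_mm2, cdf_area)$p.value, 0.01)
  # distances: mixture of uniforms over the configured bin sub-ranges
  cdf_dist <- function(x) {
    vapply(x, function(q) {
      sum(cfg$dist_bin_probs *
            pmin(pmax((q - cfg$dist_bin_ranges[, 1]) /
                        (cfg$dist_bin_ranges[, 2] - cfg$dist_bin_ranges[, 1]),
                      0), 1))
    }, 0)
  }
  expect_gt(ks.test(plan$target_dist_mm, cdf_dist)$p.value, 0.01)
  # subtype mixture
  expect_gt(chisq.test(tabulate(plan$subtype, 3L),
                       p = cfg$subtype_probs)$p.value, 0.01)
  # every distance bin is populated
  expect_equal(sort(unique(plan$dist_bin)), 0:6)
})

test_that("planted outcomes separate by effect size as designed", {
  cfg0 <- synth_config(n_cases = 10, beta = 0, seed = 1)
  cfg2 <- synth_config(n_cases = 10, seed = 1)
  set.seed(101)
  n <- 1000
  fl2 <- rlnorm(n, -2, 0.8) * rbinom(n, 1, 0.7)
  tum <- rlnorm(n, 1, 0.3)
  clin <- matrix(rnorm(n * 14), n, 14)
  # beta = 0: the label is independent of the planted FL-2 burden
  out0 <- make_outcome(fl2, tum, clin, cfg0)
  expect_lt(abs(auroc(fl2, out0$relapse_label) - 0.5), 0.05)
  out2 <- make_outcome(fl2, tum, clin, cfg2)
  expect_gte(auroc(-out2$eta, out2$relapse_label), 0.9)
  # censoring rate 0 observes every event
  cfg_nc <- synth_config(n_cases = 10, censoring_rate = 0, seed = 1)
  out_nc <- make_outcome(fl2, tum, clin, cfg_nc)
  expect_true(all(out_nc$event == 1L))
  # survival follows the protective direction
  lr <- logrank_test(out2$rfs_time_months, out2$event, out2$eta > 0)
  expect_lt(lr$p, 1e-6)
})

test_that("patch bags carry a monotone, attention-recoverable signal", {
  cfg <- synth_config(n_cases = 10, seed = 1)
  set.seed(103)
  frac <- vapply(c(-2, 0, 2), function(eta) {
    mean(vapply(1:40, function(i) mean(make_patch_bag(eta, cfg)$signal), 0))
  }, 0)
  expect_true(all(diff(frac) < 0))   # higher eta (protective) -> less signal

  # oracle attention: ranking by the signal dimensions is enriched >= 3x
  enr <- vapply(1:30, function(i) {
    bag <- make_patch_bag(2, cfg)     # low-risk case, sparse signal
    score <- bag$matrix[, 1] + bag$matrix[, 2]
    k <- max(1L, floor(nrow(bag$matrix) / 8))
    top <- order(-score)[1:k]
    base <- mean(bag$signal)
    if (base == 0 || base == 1) return(NA_real_)
    mean(bag$signal[top]) / base
  }, 0)
  expect_gte(mean(enr, na.rm = TRUE), 3)
})
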