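test_that("subtype vote follows majority with ties toward maturity", {
  m <- matrix(0L, 8, 12); m[1, 1] <- 2L
  m[3, 2:10] <- 3L
  s <- matrix(0L, 8, 12)
  s[3, 2:10] <- c(rep(1L, 5), rep(2L, 4))        # 5 Agg + 4 FL-1
  h <- tissue_heatmap(m, s)
  comp <- find_components(h, "tls")[[1]]
  expect_equal(as.integer(subtype_of(comp, h)), 1L)

  s[3, 2:10] <- c(rep(1L, 3), rep(3L, 3), rep(1L, 0), rep(2L, 3))
  h <- tissue_heatmap(m, s)                      # 3 Agg, 3 FL-2, 3 FL-1
  expect_equal(as.integer(subtype_of(find_components(h, "tls")[[1]], h)), 3L)

  s[3, 2:10] <- 3L
  h <- tissue_heatmap(m, s)
  expect_equal(names(subtype_of(find_components(h, "tls")[[1]], h)), "FL-2")
})

test_that("distance bins reproduce the printed interval edges", {
  probes <- c(-0.5, 0, 1e-9, 0.4, 0.400001, 1.0, 1.1, 2.2, 2.3, 4.5,
              4.6, 6.4, 6.5)
  expect_equal(bin_distance(probes),
               c(0, 0, 1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6))
})

test_that("area bins reproduce the printed interval edges", {
  probes <- c(0.001, 0.03, 0.031, 0.05, 0.06, 0.07, 0.08, 0.10, 0.12,
              0.15, 0.2, 0.28, 0.30)
  expect_equal(bin_area(probes), c(0, 0, 1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6))
  expect_error(bin_area(0), "> 0")
  expect_error(bin_area(-1), "> 0")
})

test_that("signed margin distance matches a brute-force boundary search", {
  # straight tumor edge at col 8; TLS centroid 3 px outside
  h <- edge_fixture(12, 11:11)
  tc <- tls_components(h)[[1]]
  expect_equal(tc$signed_margin_distance_mm, 3 * 0.064)

  # centroid 2 px deep inside tumor (carved TLS): nearest rim is its own
  # carve, so use an explicit brute-force oracle instead of the planted gap
  m <- matrix(0L, 24, 24); m[, 1:8] <- 2L
  m[12, 6] <- 3L
  s <- matrix(0L, 24, 24); s[12, 6] <- 1L
  h2 <- tissue_heatmap(m, s)
  tc2 <- tls_components(h2)[[1]]
  bnd <- which(m == 2L &
                 (col(m) == 8L | col(m) == 1L | row(m) %in% c(1L, 24L) |
                    abs(col(m) - 6L) + abs(row(m) - 12L) == 1L),
               arr.ind = TRUE)
  d_oracle <- -min(sqrt((bnd[, 1] - 12)^2 + (bnd[, 2] - 6)^2)) * 0.064
  expect_equal(tc2$signed_margin_distance_mm, d_oracle)
  expect_lt(tc2$signed_margin_distance_mm, 0)

  # centroid exactly on the boundary column
  h3 <- edge_fixture(12, 8)
  # place TLS pixel on the boundary itself: col 8 was tumor, now TLS
  expect_equal(abs(tls_components(h3)[[1]]$signed_margin_distance_mm) <=
                 0.064, TRUE)
})

test_that("distance errors without tumor and random probes match brute force", {
  m <- matrix(0L, 10, 10); m[4, 4] <- 3L
  s <- matrix(0L, 10, 10); s[4, 4] <- 1L
  expect_error(tls_components(tissue_heatmap(m, s)), "no tumor")

  set.seed(31)
  for (rep in 1:5) {
    h <- random_heatmap(18, 18, p = c(0.5, 0, 0.35, 0.15))
    if (!any(h$labels == 2L) || !any(h$labels == 3L)) next
    comps <- find_components(h, "tls")
    bnd <- tlsview:::tumor_boundary_coords(h$labels)
    for (comp in comps) {
      ctr <- comp$centroid
      d_px <- sqrt(min((bnd[, 1] - ctr[1])^2 + (bnd[, 2] - ctr[2])^2))
      expect_equal(abs(signed_margin_distance(comp, h)), d_px * 0.064,
                   tolerance = 1e-12)
    }
  }
})

test_that("the registry has exactly 226 uniquely named entries", {
  reg <- spatial_feature_registry()
  expect_length(reg, 226L)
  expect_equal(anyDuplicated(reg), 0L)
  blocks <- c(dist = 63L, area = 63L, joint = 98L, tumor = 2L)
  for (b in names(blocks))
    expect_equal(sum(startsWith(reg, paste0(b, "_"))), unname(blocks[[b]]))
})

test_that("a single known TLS fills exactly the expected registry cells", {
  # one FL-2 TLS, area 0.04 mm^2, distance ~3 mm
  pitch <- 0.1
  m <- matrix(0L, 60, 60); m[, 1:5] <- 2L
  m[20, 34:37] <- 3L               # 4 px; centroid col 35.5, 30.5 px offset
  s <- matrix(0L, 60, 60); s[m == 3L] <- 3L
  h <- tissue_heatmap(m, s, pixel_pitch_mm = pitch)
  comps <- tls_components(h)
  expect_equal(comps[[1]]$signed_margin_distance_mm, 30.5 * pitch)
  v <- build_spatial_features(comps, list(h))
  expect_length(v, 226L)
  expect_equal(unname(v["dist_22_45_fl2_count"]), 1)
  expect_equal(unname(v["dist_22_45_fl2_total_area"]), 0.04)
  expect_equal(unname(v["dist_22_45_fl2_mean_area"]), 0.04)
  expect_equal(unname(v["area_003_005_fl2_count"]), 1)
  expect_equal(unname(v["joint_22_45_003_005_count"]), 1)
  expect_equal(unname(v["joint_22_45_003_005_total_area"]), 0.04)
  # every other count cell is zero
  counts <- v[grepl("_count$", names(v))]
  expect_equal(sum(counts), 3)           # one per bin family
  expect_gt(unname(v["tumor_total_area_mm2"]), 0)
})

test_that("a case without TLS yields zero TLS blocks but tumor globals", {
  m <- matrix(0L, 20, 20); m[5:12, 5:12] <- 2L
  h <- tissue_heatmap(m)
  v <- build_spatial_features(list(), list(h))
  expect_equal(sum(v[setdiff(names(v), c("tumor_total_area_mm2",
                                         "tumor_mean_area_per_slide_mm2"))]),
               0)
  expect_equal(unname(v["tumor_total_area_mm2"]), 64 * 0.064^2)
  expect_equal(unname(v["tumor_mean_area_per_slide_mm2"]), 64 * 0.064^2)
})

test_that("triple bookkeeping: all three bin families conserve counts and area", {
  set.seed(41)
  for (rep in 1:5) {
    cfg <- synth_config(n_cases = 10, tls_mean = 5, seed = 400 + rep)
    set.seed(500 + rep)
    out <- suppressWarnings(make_heatmap(cfg, slide_id = "s1"))
    h <- postprocess(out$heatmap)
    comps <- tls_components(h)
    v <- build_spatial_features(comps, list(h))
    n_tls <- length(comps)
    expect_equal(sum(v[grepl("^dist_.*_count$", names(v))]), n_tls)
    expect_equal(sum(v[grepl("^area_.*_count$", names(v))]), n_tls)
    expect_equal(sum(v[grepl("^joint_.*_count$", names(v))]), n_tls)
    total_area <- sum(vapply(comps, function(x) x$area_mm2, 0))
    expect_equal(sum(v[grepl("^dist_.*_total_area$", names(v))]), total_area,
                 tolerance = 1e-9)
    expect_equal(sum(v[grepl("^joint_.*_total_area$", names(v))]), total_area,
                 tolerance = 1e-9)
  }
})

test_that("feature vector is invariant to slide/component order and translation", {
  cfg <- synth_config(n_cases = 10, seed = 61)
  set.seed(61)
  a <- suppressWarnings(make_heatmap(cfg, slide_id = "a"))$heatmap
  set.seed(62)
  b <- suppressWarnings(make_heatmap(cfg, slide_id = "b"))$heatmap
  pa <- postprocess(a); pb <- postprocess(b)
  ca <- tls_components(pa); cb <- tls_components(pb)
  v1 <- build_spatial_features(c(ca, cb), list(pa, pb))
  v2 <- build_spatial_features(c(rev(cb), rev(ca)), list(pb, pa))
  expect_equal(v1, v2)

  # translation: shift the whole grid content by (3, 2)
  m <- pa$labels; s <- pa$subtypes
  nr <- nrow(m)
  m2 <- matrix(0L, nr + 6, ncol(m) + 6); s2 <- matrix(0L, nr + 6, ncol(m) + 6)
  m2[4:(nr + 3), 3:(ncol(m) + 2)] <- m
  s2[4:(nr + 3), 3:(ncol(m) + 2)] <- s
  ht <- tissue_heatmap(m2, s2, slide_id = "a")
  vt <- build_spatial_features(tls_components(ht), list(ht))
  va <- build_spatial_features(ca, list(pa))
  expect_equal(vt, va)
})
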