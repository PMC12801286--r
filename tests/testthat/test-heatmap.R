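test_that("diagonal pixels form one 8-connected component", {
  m <- matrix(0L, 6, 6)
  m[2, 2] <- 2L; m[3, 3] <- 2L
  comps <- find_components(tissue_heatmap(m), "tumor")
  expect_length(comps, 1L)
  expect_equal(comps[[1]]$area_px, 2L)
})

test_that("component extraction matches a brute-force flood fill", {
  set.seed(11)
  for (rep in 1:8) {
    h <- random_heatmap()
    for (cls in c(2L, 3L)) {
      comps <- find_components(h, cls)
      oracle <- flood_components(h$labels == cls)
      expect_length(comps, length(oracle))
      # identical pixel partitions (compare sorted pixel key sets)
      key <- function(px) paste(sort(paste(px[, 1], px[, 2])), collapse = ";")
      expect_setequal(vapply(comps, function(x) key(x$pixel_coords), ""),
                      vapply(oracle, key, ""))
      # area bookkeeping: components partition the class pixels
      expect_equal(sum(vapply(comps, function(x) x$area_px, 0L)),
                   sum(h$labels == cls))
    }
  }
})

test_that("components are empty for an absent class and ordered by min row/col", {
  h <- tissue_heatmap(matrix(0L, 5, 5))
  expect_length(find_components(h, "tumor"), 0L)
  expect_error(find_components(h, 7), "unknown tissue class")

  m <- matrix(0L, 10, 10)
  m[6:7, 2:3] <- 2L
  m[2:3, 6:7] <- 2L
  comps <- find_components(tissue_heatmap(m), "tumor")
  expect_equal(vapply(comps, function(x) min(x$pixel_coords[, "row"]), 0L),
               c(2L, 6L))
})

test_that("a 3x3 TLS block is one component with correct area and centroid", {
  m <- matrix(0L, 8, 8); m[3:5, 4:6] <- 3L
  h <- tissue_heatmap(m)
  comps <- find_components(h, "tls")
  expect_length(comps, 1L)
  expect_equal(comps[[1]]$area_px, 9L)
  expect_equal(comps[[1]]$area_mm2, 9 * 0.064^2)
  expect_equal(unname(comps[[1]]$centroid), c(4, 5))
})

test_that("tumor size threshold: 19-px component removed, 20-px survives", {
  m <- matrix(0L, 30, 30)
  m[2:5, 2:6] <- 2L          # 20 px
  m[20:23, 20:24] <- 2L; m[20, 20] <- 0L   # 19 px
  p <- postprocess(tissue_heatmap(m), min_tumor_px = 20L)
  comps <- find_components(p, "tumor")
  expect_length(comps, 1L)
  expect_equal(comps[[1]]$area_px, 20L)
})

test_that("post-processing removes normal tissue and singletons, fills holes", {
  m <- matrix(0L, 14, 14)
  m[2:10, 2:10] <- 2L
  m[5:6, 5:6] <- 0L            # interior hole
  m[12, 12] <- 3L              # singleton TLS
  m[2:4, 12:13] <- 1L          # normal domain
  s <- matrix(0L, 14, 14); s[12, 12] <- 2L
  p <- postprocess(tissue_heatmap(m, s))
  expect_equal(p$labels[5, 5], 2L)        # hole filled as tumor
  expect_equal(p$labels[12, 12], 0L)      # singleton removed
  expect_true(all(p$labels != 1L))        # no normal pixels remain
  expect_true(all(p$subtypes[p$labels != 3L] == 0L))
})

test_that("an all-normal heatmap post-processes to all background", {
  p <- postprocess(tissue_heatmap(matrix(1L, 9, 9)))
  expect_true(all(p$labels == 0L))
})

test_that("hole enclosed by TLS is filled as TLS with the enclosing subtype", {
  m <- matrix(0L, 12, 12)
  m[3:9, 3:9] <- 3L; m[6, 6] <- 0L
  s <- matrix(0L, 12, 12); s[m == 3L] <- 3L
  p <- postprocess(tissue_heatmap(m, s))
  expect_equal(p$labels[6, 6], 3L)
  expect_equal(p$subtypes[6, 6], 3L)
})

test_that("post-processing is idempotent and matches a naive oracle", {
  set.seed(21)
  for (rep in 1:6) {
    h <- random_heatmap(16, 16)
    p1 <- postprocess(h)
    p2 <- postprocess(p1)
    expect_identical(p1$labels, p2$labels)
    expect_identical(p1$subtypes, p2$subtypes)
    expect_identical(p1$labels, postprocess_oracle(h$labels))
  }
})

test_that("post-processing is the identity on clean planted structures", {
  m <- matrix(0L, 30, 30)
  m[5:12, 5:12] <- 2L           # 64 px, no holes
  m[20:23, 20:24] <- 3L
  s <- matrix(0L, 30, 30); s[m == 3L] <- 2L
  h <- tissue_heatmap(m, s)
  p <- postprocess(h)
  expect_identical(p$labels, m)
  expect_identical(p$subtypes, s)
})

test_that("SSIM is 1 for identical grids and errors on shape mismatch", {
  h <- random_heatmap(10, 10)
  expect_equal(ssim(h, h), 1.0)
  const <- tissue_heatmap(matrix(2L, 9, 9))
  expect_equal(ssim(const, const), 1.0)
  expect_error(ssim(h, random_heatmap(12, 12)), "shapes differ")
})

test_that("SSIM matches an independent windowed reference implementation", {
  a8 <- matrix(c(0,3,2,1,1,3,0,2, 0,0,2,3,2,3,2,3, 2,0,3,1,2,1,0,3,
                 3,2,1,3,2,1,1,0, 0,2,3,0,3,3,1,2, 0,3,2,1,0,3,1,3,
                 2,3,3,0,1,1,1,0, 2,0,2,2,3,2,1,3),
               nrow = 8, byrow = TRUE)
  b8 <- a8; b8[3, 4] <- 0; b8[6, 6] <- 2; b8[1, 1] <- 3
  ha <- tissue_heatmap(matrix(as.integer(a8), 8, 8))
  hb <- tissue_heatmap(matrix(as.integer(b8), 8, 8))
  # reference value from scikit-image structural_similarity
  # (win_size = 7, uniform window, data_range = 3)
  expect_equal(ssim(ha, hb), 0.9656333949555955, tolerance = 1e-10)
})

test_that("heatmap invariants are enforced", {
  expect_error(tissue_heatmap(matrix(5L, 3, 3)), "labels")
  m <- matrix(0L, 3, 3); s <- matrix(0L, 3, 3); s[1, 1] <- 2L
  expect_error(tissue_heatmap(m, s), "subtypes")
  expect_error(tissue_heatmap(matrix(0L, 3, 3), pixel_pitch_mm = 0),
               "pixel_pitch_mm")
})

test_that("PNG and text round trips preserve the heatmap", {
  h <- random_heatmap(15, 12)
  pre <- file.path(withr::local_tempdir(), "hm")
  write_heatmap(h, pre)
  h2 <- read_heatmap(pre)
  expect_identical(h2$labels, h$labels)
  expect_identical(h2$subtypes, h$subtypes)
  expect_equal(h2$pixel_pitch_mm, h$pixel_pitch_mm)

  tf <- file.path(withr::local_tempdir(), "grid.txt")
  writeLines(apply(h$labels, 1L, paste, collapse = " "), tf)
  h3 <- read_heatmap_text(tf)
  expect_identical(h3$labels, h$labels)
})
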