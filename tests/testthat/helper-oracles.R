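# Independent oracles and shared fixtures.

# naive reimplementation of the full post-processing for small grids
postprocess_oracle <- function(labels, min_tumor_px = 20L) {
  labels[labels == 1L] <- 0L
  for (cls in c(2L, 3L)) {
    for (px in flood_components(labels == cls)) {
      min_px <- if (cls == 2L) max(2L, min_tumor_px) else 2L
      if (nrow(px) < min_px) labels[px] <- 0L
    }
  }
  nr <- nrow(labels); nc <- ncol(labels)
  base <- labels
  for (px in flood_components(base == 0L, connectivity = 4)) {
    if (any(px[, 1] %in% c(1L, nr)) || any(px[, 2] %in% c(1L, nc))) next
    nb <- integer(0)
    for (i in seq_len(nrow(px)))
      for (dr in -1:1) for (dc in -1:1) {
        rr <- px[i, 1] + dr; cc <- px[i, 2] + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc)
          nb <- c(nb, base[rr, cc])
      }
    nb <- nb[nb > 0L]
    if (length(nb)) {
      counts <- tabulate(nb, 3L)
      labels[px] <- if (counts[2L] >= counts[3L]) 2L else 3L
    }
  }
  labels
}

# brute-force flood fill, deliberately naive (8- or 4-connected)
flood_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  comps <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || seen[r, c]) next
    stack <- list(c(r, c)); seen[r, c] <- TRUE
    px <- list()
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      px[[length(px) + 1L]] <- p
      steps <- if (connectivity == 8)
        expand.grid(dr = -1:1, dc = -1:1)
      else data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
      for (k in seq_len(nrow(steps))) {
        rr <- p[1] + steps$dr[k]; cc <- p[2] + steps$dc[k]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
    comps[[length(comps) + 1L]] <- do.call(rbind, px)
  }
  comps
}

# random small heatmap for property tests
random_heatmap <- function(nr = 24, nc = 24, p = c(0.6, 0.1, 0.2, 0.1)) {
  labels <- matrix(sample(0:3, nr * nc, replace = TRUE, prob = p), nr, nc)
  subtypes <- matrix(0L, nr, nc)
  subtypes[labels == 3L] <- sample(1:3, sum(labels == 3L), replace = TRUE)
  tissue_heatmap(labels, subtypes)
}

# straight-edge tumor fixture with one TLS block at a known offset
edge_fixture <- function(tls_rows, tls_cols, subtype = 3L, nr = 24, nc = 24) {
  labels <- matrix(0L, nr, nc)
  labels[, 1:8] <- 2L
  subtypes <- matrix(0L, nr, nc)
  labels[tls_rows, tls_cols] <- 3L
  subtypes[tls_rows, tls_cols] <- subtype
  tissue_heatmap(labels, subtypes)
}

# small deterministic cohort for protocol tests (no image synthesis)
toy_cohort <- function(n = 24, seed = 5, d_m = 8, informative = TRUE) {
  set.seed(seed)
  spatial <- matrix(rnorm(n * 226), n, 226)
  colnames(spatial) <- spatial_feature_registry()
  labels <- rbinom(n, 1, 0.5)
  if (informative)
    spatial[, 1:10] <- spatial[, 1:10] + 2 * labels
  cases <- data.frame(case_id = sprintf("t%02d", 1:n),
                      relapse_label = labels,
                      rfs_time_months = rexp(n, 1 / 40) + 1,
                      event = rbinom(n, 1, 0.8),
                      act_flag = rbinom(n, 1, 0.5),
                      stringsAsFactors = FALSE)
  morph <- lapply(1:n, function(i) {
    structure(list(centers = matrix(rnorm(7 * d_m) + labels[i], 7, d_m),
                   case_id = cases$case_id[i], seed = seed, empty = FALSE),
              class = "morph_bag")
  })
  clinical <- matrix(rnorm(n * 14), n, 14)
  tls_cohort(cases, spatial = spatial, morph = morph, clinical = clinical,
             bags = lapply(1:n, function(i) matrix(rnorm(12 * 6), 12, 6)))
}

# central finite-difference gradient of scalar-valued fn at x (matrix)
num_grad <- function(fn, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}
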