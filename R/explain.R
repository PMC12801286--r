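# Interpretability: top-attended instances, patch clustering, and exact
# grouped Shapley attribution for the spatial branch.

#' Top-attended instances
#'
#' Ranks instances by attention score; ties break toward the smaller
#' instance index, and `k` is truncated to the bag size.
#'
#' @param scores normalized attention scores.
#' @param k number of instances to keep (default 50).
#' @param ids optional instance identifiers (default indices).
#' @return The `ids` of the top-k instances, highest score first.
#' @export
top_attention_tiles <- function(scores, k = 50L, ids = seq_along(scores)) {
  stopifnot(length(ids) == length(scores))
  ord <- order(-scores, seq_along(scores))
  ids[ord[seq_len(min(k, length(scores)))]]
}

#' Cluster selected patch features
#'
#' k-means (k-means++ seeding, Lloyd) over the features of the selected
#' tiles, as used to summarize the morphology of high-attention patches.
#' When fewer tiles than clusters are given, k is reduced with a warning.
#'
#' @param features matrix of tile features (one row per tile).
#' @param k number of clusters (default 5).
#' @param seed RNG seed.
#' @return List with `assignment`, `sizes` (per-cluster counts) and
#'   `centers`.
#' @export
cluster_patches <- function(features, k = 5L, seed = 1L) {
  X <- as.matrix(features)
  if (nrow(X) < k) {
    warning(sprintf("only %d tiles; reducing k from %d", nrow(X), k))
    k <- nrow(X)
  }
  if (k == 1L) {
    return(list(assignment = rep(1L, nrow(X)), sizes = nrow(X),
                centers = matrix(colMeans(X), 1L)))
  }
  fit <- with_seed(seed, {
    f <- NULL
    for (try in 1:5) {
      init <- kmeanspp_centers(X, k)
      f <- tryCatch(stats::kmeans(X, centers = init, iter.max = 300L,
                                  algorithm = "Lloyd"),
                    error = function(e) NULL)
      if (!is.null(f)) break
    }
    if (is.null(f)) stop("k-means failed on the selected tiles")
    f
  })
  list(assignment = fit$cluster, sizes = as.integer(fit$size),
       centers = fit$centers)
}

#' Default feature grouping for Shapley attribution
#'
#' Partitions the 226 spatial features into 11 groups: one per distance bin
#' (that bin's distance x subtype block plus its joint distance x area
#' block), one per subtype for the area-bin block, and one for the tumor
#' globals.
#'
#' @return Named list of integer index vectors partitioning 1:226.
#' @export
spatial_feature_groups <- function() {
  reg <- spatial_feature_registry()
  groups <- list()
  for (i in seq_along(DIST_BIN_LABELS)) {
    d <- DIST_BIN_LABELS[i]
    groups[[paste0("dist_", d)]] <-
      which(startsWith(reg, paste0("dist_", d, "_")) |
            startsWith(reg, paste0("joint_", d, "_")))
  }
  for (s in SUBTYPE_LABELS) {
    groups[[paste0("area_", s)]] <-
      which(startsWith(reg, "area_") & grepl(paste0("_", s, "_"), reg))
  }
  groups$tumor <- which(startsWith(reg, "tumor_"))
  groups
}

#' Exact grouped Shapley attribution for the spatial branch
#'
#' Exact Shapley values over feature groups by full enumeration of the 2^g
#' coalitions: out-of-coalition groups are replaced by the baseline values
#' (default: cohort mean vector), in-coalition groups keep the explained
#' case's values. The attributions satisfy the efficiency axiom:
#' they sum to prediction(x) - prediction(baseline).
#'
#' @param f prediction function mapping a matrix of 226-wide rows to a
#'   numeric vector (e.g. ensemble relapse probability).
#' @param x the spatial feature vector to explain (length 226).
#' @param baseline reference vector, typically the cohort mean.
#' @param groups named list of index vectors partitioning the features;
#'   at most 12 groups (enumeration bound). Default
#'   [spatial_feature_groups()].
#' @return An `attribution_report`: list with `values` (named per group),
#'   `direction` (`"favorable"` for negative risk attribution,
#'   `"unfavorable"` otherwise), `prediction`, `baseline_prediction`,
#'   `groups`.
#' @export
shapley_spb <- function(f, x, baseline, groups = spatial_feature_groups()) {
  x <- as.numeric(x); baseline <- as.numeric(baseline)
  stopifnot(length(x) == length(baseline))
  g <- length(groups)
  if (g > 12L) stop("at most 12 feature groups are supported (2^g enumeration)")
  idx_all <- sort(unlist(groups, use.names = FALSE))
  if (!identical(idx_all, seq_along(x)))
    stop("groups must partition the feature vector")

  n_coal <- 2L^g
  # coalition membership matrix: row = coalition, col = group
  member <- matrix(FALSE, n_coal, g)
  for (j in seq_len(g))
    member[, j] <- bitwAnd(seq_len(n_coal) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  X <- matrix(baseline, n_coal, length(x), byrow = TRUE)
  for (j in seq_len(g)) {
    rows <- which(member[, j])
    X[rows, groups[[j]]] <- matrix(x[groups[[j]]], length(rows),
                                   length(groups[[j]]), byrow = TRUE)
  }
  v <- f(X)
  if (length(v) != n_coal) stop("prediction function must return one value per row")

  fact <- factorial(0:g)
  phi <- numeric(g)
  sizes <- rowSums(member)
  for (j in seq_len(g)) {
    without <- which(!member[, j])
    with_j <- without + bitwShiftL(1L, j - 1L)
    s <- sizes[without]
    w <- fact[s + 1L] * fact[g - s] / fact[g + 1L]
    phi[j] <- sum(w * (v[with_j] - v[without]))
  }
  names(phi) <- names(groups)
  structure(list(values = phi,
                 direction = ifelse(phi < 0, "favorable", "unfavorable"),
                 prediction = v[n_coal],
                 baseline_prediction = v[1L],
                 groups = groups),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat(sprintf("grouped Shapley attribution: prediction %.4f, baseline %.4f\n",
              x$prediction, x$baseline_prediction))
  ord <- order(-abs(x$values))
  df <- data.frame(group = names(x$values)[ord],
                   value = round(x$values[ord], 5),
                   direction = x$direction[ord], row.names = NULL)
  print(df)
  invisible(x)
}

#' Maturity-by-outcome contingency summary
#'
#' Cross-tabulates the predicted subtype of each case's highest-attention
#' TLS against the outcome group, with a chi-squared association test.
#'
#' @param subtype per-case subtype codes or names.
#' @param outcome per-case outcome group (e.g. relapse yes/no).
#' @return List with `table`, `chisq`, `p`.
#' @export
maturity_table <- function(subtype, outcome) {
  tab <- table(subtype = subtype, outcome = outcome)
  ct <- suppressWarnings(stats::chisq.test(tab))
  list(table = tab, chisq = unname(ct$statistic), p = ct$p.value)
}
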