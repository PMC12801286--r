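# Morphological branch: embed TLS regions, cluster per case into 7
# representative centers, aggregate with gated attention.

# fixed projection so the toy encoder is reproducible across sessions
TOY_ENCODER_SEED <- 773301L

#' Handcrafted TLS shape/subtype encoder
#'
#' A deterministic stand-in for a learned TLS-image encoder, satisfying the
#' pluggable encoder contract (component, heatmap) -> fixed-width vector.
#' It describes a TLS component by area (mm^2), rasterized perimeter (pixel
#' edge count), circularity 4*pi*A/P^2, subtype one-hot, and signed margin
#' distance (mm), then expands to `d_m` dimensions through a fixed random
#' projection with tanh squashing. Translation of the component leaves the
#' embedding unchanged.
#'
#' @param tc a `tls_component` (see [tls_components()]).
#' @param h the `tissue_heatmap` the component came from (unused beyond the
#'   contract; all descriptors are precomputed on the component).
#' @param d_m embedding width (default 64).
#' @return Numeric vector of length `d_m`.
#' @export
toy_encoder <- function(tc, h = NULL, d_m = 64L) {
  cc <- tc$component
  per <- component_perimeter(cc)
  circ <- 4 * pi * cc$area_px / per^2
  desc <- c(cc$area_mm2, per / 100, circ,
            as.numeric(seq_len(3L) == as.integer(tc$subtype)),
            tc$signed_margin_distance_mm)
  proj <- with_seed(TOY_ENCODER_SEED,
                    matrix(stats::rnorm(7L * d_m, sd = 1 / sqrt(7)), d_m, 7L))
  as.vector(tanh(proj %*% desc))
}

# perimeter = number of exposed pixel edges (4-neighborhood / grid border)
component_perimeter <- function(cc) {
  coords <- cc$pixel_coords
  key <- paste(coords[, 1], coords[, 2])
  inside <- new.env(parent = emptyenv())
  for (k in key) assign(k, TRUE, envir = inside)
  per <- 0L
  for (i in seq_len(nrow(coords))) {
    r <- coords[i, 1]; c <- coords[i, 2]
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      if (!exists(paste(r + d[1], c + d[2]), envir = inside,
                  inherits = FALSE))
        per <- per + 1L
    }
  }
  per
}

kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- sample.int(n, 1L)
  for (j in 2:k) {
    d2 <- apply(X, 1L, function(row)
      min(colSums((t(X[idx, , drop = FALSE]) - row)^2)))
    if (sum(d2) == 0) idx <- c(idx, sample.int(n, 1L))
    else idx <- c(idx, sample.int(n, 1L, prob = d2))
  }
  X[idx, , drop = FALSE]
}

#' Cluster a case's TLS embeddings into 7 representative centers
#'
#' k-means (k-means++ seeding, Lloyd iterations, at most 300, tolerance
#' 1e-6) over the case's TLS embeddings; the cluster centers are the case's
#' representative lymphoid features, giving every case a fixed 7 x d_m
#' representation so downstream batches have constant shape. Degenerate
#' cases: with exactly k embeddings the inputs themselves are the centers;
#' with fewer than k (or fewer than k distinct) rows the available rows are
#' repeated cyclically to k; an empty list yields an all-zero bag flagged
#' `empty`.
#'
#' @param embeddings list of equal-length numeric vectors, or a matrix with
#'   one embedding per row.
#' @param k number of centers (default 7).
#' @param seed RNG seed (recorded in the output).
#' @param case_id identifier carried through.
#' @param d_m embedding width, required only for the empty case.
#' @return A `morph_bag`: list with `centers` (k x d_m), `case_id`, `seed`,
#'   `empty`.
#' @export
cluster_case <- function(embeddings, k = 7L, seed = 1L, case_id = "case",
                         d_m = 64L) {
  X <- if (is.matrix(embeddings)) embeddings else do.call(rbind, embeddings)
  if (is.null(X) || nrow(X) == 0L) {
    warning(sprintf("case '%s' has no TLS embeddings; zero morph bag",
                    case_id))
    return(structure(list(centers = matrix(0, k, d_m), case_id = case_id,
                          seed = seed, empty = TRUE), class = "morph_bag"))
  }
  n <- nrow(X)
  centers <-
    if (n <= k) {
      X[rep_len(seq_len(n), k), , drop = FALSE]
    } else {
      Xu <- unique(X)
      if (nrow(Xu) <= k) {
        Xu[rep_len(seq_len(nrow(Xu)), k), , drop = FALSE]
      } else {
        with_seed(seed, {
          fit <- NULL
          for (try in 1:5) {
            init <- kmeanspp_centers(X, k)
            fit <- tryCatch(
              stats::kmeans(X, centers = init, iter.max = 300L,
                            algorithm = "Lloyd"),
              error = function(e) NULL)
            if (!is.null(fit)) break
          }
          if (is.null(fit)) stop("k-means failed to converge on this case")
          fit$centers
        })
      }
    }
  dimnames(centers) <- NULL
  structure(list(centers = centers, case_id = case_id, seed = seed,
                 empty = FALSE), class = "morph_bag")
}

#' Aggregate a morph bag with gated attention
#'
#' Gated-attention pooling over the case's 7 cluster centers, yielding the
#' final morphological representation of the case. Permutation of center
#' order permutes the scores and leaves the pooled vector unchanged.
#'
#' @param bag a `morph_bag`.
#' @param params an [attention_params()] list sized for the center width.
#' @return List with `r_m` (pooled vector) and `scores`.
#' @export
aggregate_morph <- function(bag, params) {
  if (ncol(bag$centers) != nrow(params$W1))
    stop("center width does not match attention parameters")
  g <- gated_attention(bag$centers, params)
  list(r_m = g$pooled, scores = g$scores)
}

#' Case-level morph bag from heatmaps
#'
#' Convenience wrapper: extracts TLS components from (post-processed)
#' heatmaps, embeds each with the encoder, and clusters into the
#' representative centers.
#'
#' @param heatmaps list of post-processed `tissue_heatmap` for one case.
#' @param encoder encoder function (component, heatmap, d_m) -> vector;
#'   default [toy_encoder()].
#' @param d_m embedding width.
#' @param k number of centers.
#' @param seed RNG seed for clustering.
#' @param case_id identifier.
#' @return A `morph_bag`.
#' @export
case_morph_bag <- function(heatmaps, encoder = toy_encoder, d_m = 64L,
                           k = 7L, seed = 1L, case_id = "case") {
  embs <- list()
  for (h in heatmaps) {
    for (tc in tls_components(h))
      embs[[length(embs) + 1L]] <- encoder(tc, h, d_m)
  }
  cluster_case(embs, k = k, seed = seed, case_id = case_id, d_m = d_m)
}
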