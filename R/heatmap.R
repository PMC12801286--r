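#' Tissue label heatmap
#'
#' The common currency of the pipeline: a per-slide integer label grid in
#' which each cell is one tile of the source slide classified as background
#' (0), normal tissue (1), tumor (2) or tertiary lymphoid structure, TLS (3).
#' A parallel subtype grid refines TLS pixels into maturity stages:
#' 1 = Agg (aggregate), 2 = FL-1 (primary follicle), 3 = FL-2 (secondary
#' follicle). The physical edge length of one heatmap pixel defaults to
#' 0.064 mm (a 256-pixel tile at 0.25 um/px).
#'
#' @param labels integer matrix with values in 0:3.
#' @param subtypes integer matrix of the same shape; nonzero exactly where
#'   `labels == 3`, values in 1:3. Defaults to all-Agg on TLS pixels.
#' @param pixel_pitch_mm physical pixel edge length in mm (> 0).
#' @param slide_id character scalar identifying the slide.
#' @return An object of class `tissue_heatmap`.
#' @export
tissue_heatmap <- function(labels, subtypes = NULL, pixel_pitch_mm = 0.064,
                           slide_id = "slide") {
  labels <- as_label_matrix(labels, "labels")
  if (is.null(subtypes)) {
    subtypes <- matrix(0L, nrow(labels), ncol(labels))
    subtypes[labels == 3L] <- 1L
  }
  subtypes <- as_label_matrix(subtypes, "subtypes")
  h <- structure(list(labels = labels, subtypes = subtypes,
                      pixel_pitch_mm = as.numeric(pixel_pitch_mm),
                      slide_id = as.character(slide_id)),
                 class = "tissue_heatmap")
  validate_heatmap(h)
  h
}

as_label_matrix <- function(x, what) {
  if (!is.matrix(x)) stop(sprintf("'%s' must be a matrix", what))
  storage.mode(x) <- "integer"
  x
}

validate_heatmap <- function(h) {
  stopifnot(inherits(h, "tissue_heatmap"))
  if (!all(dim(h$labels) == dim(h$subtypes)))
    stop("labels and subtypes grids must share shape")
  if (!all(h$labels %in% 0:3)) stop("labels must be in {0,1,2,3}")
  if (!all(h$subtypes %in% 0:3)) stop("subtypes must be in {0,1,2,3}")
  if (any((h$subtypes != 0L) != (h$labels == 3L)))
    stop("subtypes must be nonzero exactly where labels == 3 (TLS)")
  if (!is.finite(h$pixel_pitch_mm) || h$pixel_pitch_mm <= 0)
    stop("pixel_pitch_mm must be > 0")
  invisible(h)
}

#' @export
print.tissue_heatmap <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:3,
                      labels = c("background", "normal", "tumor", "TLS")))
  cat(sprintf("tissue_heatmap '%s': %d x %d px @ %.3f mm/px\n",
              x$slide_id, nrow(x$labels), ncol(x$labels), x$pixel_pitch_mm))
  print(tab)
  invisible(x)
}

TISSUE_CLASSES <- c(background = 0L, normal = 1L, tumor = 2L, tls = 3L)
TLS_SUBTYPES <- c(Agg = 1L, `FL-1` = 2L, `FL-2` = 3L)

# Connected-component labeling of a logical mask; returns an integer matrix
# of component ids (0 outside the mask). The 4-connected pass is delegated
# to EBImage::bwlabel; 8-connectivity is obtained by merging labels that
# touch diagonally (union-find over the label ids).
label_mask <- function(mask, connectivity = 8) {
  storage.mode(mask) <- "integer"
  lab <- EBImage::bwlabel(mask)
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (connectivity == 8 && nlab > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]      # down-right diagonal
    a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]      # down-left diagonal
    pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                   cbind(as.vector(a2), as.vector(b2)))
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      parent <- seq_len(nlab)
      find <- function(x) {
        while (parent[x] != x) {
          parent[x] <<- parent[parent[x]]
          x <- parent[x]
        }
        x
      }
      for (i in seq_len(nrow(pairs))) {
        ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(nlab), find, 1L)
      map <- match(root, sort(unique(root)))
      nz <- lab > 0L
      lab[nz] <- map[lab[nz]]
    }
  }
  lab
}

#' Connected components of one tissue class
#'
#' Partitions the pixels of a tissue class into 8-connected components,
#' ordered deterministically by (min row, min col) of each component.
#'
#' @param h a `tissue_heatmap`.
#' @param tissue_class class id in 0:3 or one of
#'   `"background"`, `"normal"`, `"tumor"`, `"tls"`.
#' @return A list of `connected_component` objects, each with fields
#'   `label_class`, `pixel_coords` (two-column matrix of row/col),
#'   `area_px`, `area_mm2`, `centroid` and `slide_id`.
#' @export
find_components <- function(h, tissue_class) {
  validate_heatmap(h)
  cls <- resolve_class(tissue_class)
  lab <- label_mask(h$labels == cls, connectivity = 8)
  components_from_labels(lab, cls, h)
}

resolve_class <- function(tissue_class) {
  if (is.character(tissue_class)) {
    key <- tolower(tissue_class)
    if (!key %in% names(TISSUE_CLASSES))
      stop(sprintf("unknown tissue class '%s'", tissue_class))
    return(TISSUE_CLASSES[[key]])
  }
  cls <- as.integer(tissue_class)
  if (length(cls) != 1L || is.na(cls) || !cls %in% 0:3)
    stop(sprintf("unknown tissue class id '%s'", tissue_class))
  cls
}

components_from_labels <- function(lab, cls, h) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  nr <- nrow(lab)
  comps <- lapply(ids, function(id) {
    idx <- which(lab == id)
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    structure(list(
      label_class = cls,
      pixel_coords = cbind(row = rows, col = cols),
      area_px = length(idx),
      area_mm2 = length(idx) * h$pixel_pitch_mm^2,
      centroid = c(row = mean(rows), col = mean(cols)),
      slide_id = h$slide_id
    ), class = "connected_component")
  })
  ord <- order(vapply(comps, function(x) min(x$pixel_coords[, "row"]), 0L),
               vapply(comps, function(x) min(x$pixel_coords[, "col"]), 0L))
  comps[ord]
}

#' Heatmap post-processing
#'
#' Cleans isolated mispredictions before feature construction: normal-tissue
#' pixels are cleared to background, single-pixel components of any tissue
#' class are removed, tumor components smaller than `min_tumor_px` are
#' removed, and interior holes of the remaining tumor and TLS components are
#' filled with the enclosing class. The operation is idempotent.
#'
#' A hole is a 4-connected background region that does not touch the grid
#' border; it takes the majority class of its adjacent non-background pixels
#' (ties toward tumor). Holes filled as TLS take the majority subtype of the
#' adjacent TLS pixels (ties toward the more mature stage).
#'
#' @param h a `tissue_heatmap`.
#' @param min_tumor_px minimum surviving tumor-component area in pixels
#'   (default 20).
#' @return A post-processed `tissue_heatmap`.
#' @export
postprocess <- function(h, min_tumor_px = 20L) {
  validate_heatmap(h)
  if (min_tumor_px < 1) stop("min_tumor_px must be >= 1")
  labels <- h$labels
  subtypes <- h$subtypes

  labels[labels == 1L] <- 0L     # normal tissue domains removed outright

  for (cls in c(2L, 3L)) {
    lab <- label_mask(labels == cls, 8)
    if (!any(lab > 0L)) next
    sizes <- tabulate(lab[lab > 0L])
    min_px <- if (cls == 2L) max(2L, as.integer(min_tumor_px)) else 2L
    drop <- which(sizes < min_px)
    if (length(drop)) labels[lab %in% drop] <- 0L
  }

  # hole filling: enclosed background regions inherit the surrounding class
  bg <- label_mask(labels == 0L, 4)
  if (any(bg > 0L)) {
    nr <- nrow(labels); nc <- ncol(labels)
    border_ids <- unique(c(bg[1, ], bg[nr, ], bg[, 1], bg[, nc]))
    hole_ids <- setdiff(unique(as.vector(bg)), c(0L, border_ids))
    base <- labels   # fills are decided against the pre-fill state
    for (id in hole_ids) {
      idx <- which(bg == id)
      nb <- neighbor_values(base, idx)
      nb <- nb[nb > 0L]
      if (!length(nb)) next
      counts <- tabulate(nb, nbins = 3L)
      fill <- if (counts[2L] >= counts[3L]) 2L else 3L
      labels[idx] <- fill
      if (fill == 3L) {
        snb <- neighbor_values(subtypes, idx)
        snb <- snb[snb > 0L]
        sc <- tabulate(snb, nbins = 3L)
        subtypes[idx] <- max(which(sc == max(sc)))  # tie -> more mature
      }
    }
  }

  subtypes[labels != 3L] <- 0L
  out <- h
  out$labels <- labels
  out$subtypes <- subtypes
  validate_heatmap(out)
}

# values of the 8-neighbors of the given linear indices (off-grid dropped)
neighbor_values <- function(m, idx) {
  nr <- nrow(m); nc <- ncol(m)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  out <- integer(0)
  for (k in 1:8) {
    rr <- r + dr[k]; cc <- c + dc[k]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    if (any(ok)) out <- c(out, m[(cc[ok] - 1L) * nr + rr[ok]])
  }
  out
}

#' Structural similarity of two heatmaps
#'
#' Windowed structural similarity (SSIM) between two label grids treated as
#' intensity images: uniform square window (default 7), sample covariance,
#' stabilizing constants C1 = (0.01 L)^2 and C2 = (0.03 L)^2 with
#' L = data range = the maximum label present. Used to audit that
#' post-processing preserves the spatial structure of the heatmap.
#'
#' @param a,b `tissue_heatmap` objects of the same shape.
#' @param win odd window edge length (default 7).
#' @return Mean SSIM over all fully-contained windows, in \[-1, 1\].
#' @export
ssim <- function(a, b, win = 7L) {
  validate_heatmap(a); validate_heatmap(b)
  if (!all(dim(a$labels) == dim(b$labels))) stop("heatmap shapes differ")
  X <- a$labels; Y <- b$labels
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  if (win %% 2L != 1L) stop("win must be odd")
  if (min(dim(X)) < win)
    stop(sprintf("grid smaller than the %d-pixel SSIM window", win))
  L <- max(X, Y)
  if (L == 0) return(1.0)   # two all-background grids are identical
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  n <- win * win
  nr <- nrow(X) - win + 1L; nc <- ncol(X) - win + 1L
  SA <- SB <- SAA <- SBB <- SAB <- matrix(0, nr, nc)
  for (i in 0:(win - 1L)) for (j in 0:(win - 1L)) {
    sa <- X[(1L + i):(nr + i), (1L + j):(nc + j), drop = FALSE]
    sb <- Y[(1L + i):(nr + i), (1L + j):(nc + j), drop = FALSE]
    SA <- SA + sa; SB <- SB + sb
    SAA <- SAA + sa * sa; SBB <- SBB + sb * sb; SAB <- SAB + sa * sb
  }
  ux <- SA / n; uy <- SB / n
  vx <- (SAA - n * ux^2) / (n - 1)
  vy <- (SBB - n * uy^2) / (n - 1)
  cxy <- (SAB - n * ux * uy) / (n - 1)
  num <- (2 * ux * uy + C1) * (2 * cxy + C2)
  den <- (ux^2 + uy^2 + C1) * (vx + vy + C2)
  mean(num / den)
}
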