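#' @name spatial-binning
#' @title Distance and area binning for TLS spatial features
#'
#' @description
#' TLS-to-tumor-margin distances (mm, signed: negative inside tumor) are
#' categorized into seven non-overlapping intervals:
#' \eqn{\le 0}, (0, 0.4], (0.4, 1.0], (1.0, 2.2], (2.2, 4.5], (4.5, 6.4]
#' and > 6.4 mm. TLS areas (mm^2) use seven intervals:
#' (0, 0.03], (0.03, 0.05], (0.05, 0.07], (0.07, 0.10], (0.10, 0.15],
#' (0.15, 0.28] and > 0.28 mm^2.
NULL

DIST_EDGES_MM <- c(0, 0.4, 1.0, 2.2, 4.5, 6.4)
AREA_EDGES_MM2 <- c(0.03, 0.05, 0.07, 0.10, 0.15, 0.28)
DIST_BIN_LABELS <- c("le0", "0_04", "04_10", "10_22", "22_45", "45_64", "gt64")
AREA_BIN_LABELS <- c("0_003", "003_005", "005_007", "007_010", "010_015",
                     "015_028", "gt028")
SUBTYPE_LABELS <- c("agg", "fl1", "fl2")

#' @rdname spatial-binning
#' @param d signed margin distance in mm (finite).
#' @return Bin index 0..6.
#' @export
bin_distance <- function(d) {
  stopifnot(all(is.finite(d)))
  vapply(d, function(x) sum(x > DIST_EDGES_MM), 0L)
}

#' @rdname spatial-binning
#' @param a TLS area in mm^2 (> 0).
#' @export
bin_area <- function(a) {
  stopifnot(all(is.finite(a)))
  if (any(a <= 0)) stop("area must be > 0")
  vapply(a, function(x) sum(x > AREA_EDGES_MM2), 0L)
}

#' TLS subtype of a connected component
#'
#' Majority vote over the component's subtype pixels; ties break toward the
#' more mature stage (FL-2 > FL-1 > Agg).
#'
#' @param comp a `connected_component` of class TLS.
#' @param h the `tissue_heatmap` it came from.
#' @return Integer subtype code 1 (Agg), 2 (FL-1) or 3 (FL-2), named.
#' @export
subtype_of <- function(comp, h) {
  validate_heatmap(h)
  vals <- h$subtypes[comp$pixel_coords]
  vals <- vals[vals > 0L]
  if (!length(vals)) stop("component has no nonzero subtype pixels")
  counts <- tabulate(vals, nbins = 3L)
  code <- max(which(counts == max(counts)))
  structure(code, names = names(TLS_SUBTYPES)[code])
}

# tumor mask with enclosed non-tumor pockets filled; defines "inside tumor"
# for the distance sign (a TLS carved out of a tumor interior counts as
# inside even though its own pixels are not tumor-class)
tumor_filled_mask <- function(labels) {
  tumor <- labels == 2L
  if (!any(tumor)) return(tumor)
  bg <- label_mask(!tumor, 4)
  nr <- nrow(labels); nc <- ncol(labels)
  border_ids <- unique(c(bg[1, ], bg[nr, ], bg[, 1], bg[, nc]))
  hole_ids <- setdiff(unique(as.vector(bg)), c(0L, border_ids))
  for (id in hole_ids) tumor[bg == id] <- TRUE
  tumor
}

# tumor boundary pixels: tumor pixels with a non-tumor 4-neighbor or at the
# grid border
tumor_boundary_coords <- function(labels) {
  tumor <- labels == 2L
  if (!any(tumor)) return(NULL)
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- tumor
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)]
  up <- pad[1:nr, 2:(nc + 1L)]; dn <- pad[3:(nr + 2L), 2:(nc + 1L)]
  lf <- pad[2:(nr + 1L), 1:nc]; rt <- pad[2:(nr + 1L), 3:(nc + 2L)]
  boundary <- inner & !(up & dn & lf & rt)
  which(boundary, arr.ind = TRUE)
}

#' Signed distance from a TLS centroid to the tumor margin
#'
#' Euclidean distance in mm (via the pixel pitch) from the component's
#' centroid to the nearest tumor-boundary pixel; negative when the centroid
#' lies inside a tumor region (enclosed pockets count as inside).
#'
#' @param comp a `connected_component` (TLS) or anything with a `centroid`
#'   field in (row, col) pixel coordinates.
#' @param h a post-processed `tissue_heatmap` containing at least one tumor
#'   pixel.
#' @return Signed distance in mm.
#' @export
signed_margin_distance <- function(comp, h) {
  validate_heatmap(h)
  bnd <- tumor_boundary_coords(h$labels)
  if (is.null(bnd))
    stop(sprintf("slide '%s' has no tumor pixels; margin distance undefined",
                 h$slide_id))
  ctr <- comp$centroid
  d_px <- sqrt(min((bnd[, 1] - ctr[1])^2 + (bnd[, 2] - ctr[2])^2))
  d_mm <- d_px * h$pixel_pitch_mm
  nr <- nrow(h$labels); nc <- ncol(h$labels)
  pr <- min(max(floor(ctr[1] + 0.5), 1L), nr)
  pc <- min(max(floor(ctr[2] + 0.5), 1L), nc)
  inside <- tumor_filled_mask(h$labels)[pr, pc]
  unname(if (inside) -d_mm else d_mm)
}

#' Extract TLS components with subtype and margin distance
#'
#' Finds all TLS connected components of a (post-processed) heatmap and
#' annotates each with its majority subtype, area and signed margin
#' distance.
#'
#' @param h a post-processed `tissue_heatmap`.
#' @return List of `tls_component` objects (fields: `component`, `subtype`,
#'   `area_mm2`, `signed_margin_distance_mm`, `slide_id`).
#' @export
tls_components <- function(h) {
  comps <- find_components(h, "tls")
  lapply(comps, function(cc) {
    structure(list(
      component = cc,
      subtype = subtype_of(cc, h),
      area_mm2 = cc$area_mm2,
      signed_margin_distance_mm = signed_margin_distance(cc, h),
      slide_id = h$slide_id
    ), class = "tls_component")
  })
}

#' The 226-entry spatial feature registry
#'
#' Canonical named layout of the spatial feature vector:
#' \itemize{
#'   \item 7 distance bins x 3 subtypes x (count, total area, mean area) = 63
#'   \item 7 area bins x 3 subtypes x (count, total area, mean area) = 63
#'   \item 7 distance bins x 7 area bins x (count, total area) = 98
#'   \item tumor total area and mean tumor area per slide = 2
#' }
#'
#' @return Character vector of 226 feature names, with attribute
#'   `registry_version`.
#' @export
spatial_feature_registry <- function() {
  nm <- character(0)
  for (d in DIST_BIN_LABELS) for (s in SUBTYPE_LABELS)
    nm <- c(nm, paste0("dist_", d, "_", s, c("_count", "_total_area", "_mean_area")))
  for (a in AREA_BIN_LABELS) for (s in SUBTYPE_LABELS)
    nm <- c(nm, paste0("area_", a, "_", s, c("_count", "_total_area", "_mean_area")))
  for (d in DIST_BIN_LABELS) for (a in AREA_BIN_LABELS)
    nm <- c(nm, paste0("joint_", d, "_", a, c("_count", "_total_area")))
  nm <- c(nm, "tumor_total_area_mm2", "tumor_mean_area_per_slide_mm2")
  structure(nm, registry_version = "1.0")
}

#' Build the case-level 226-dimensional spatial feature vector
#'
#' Pools TLS component counts and areas over all slides of a case into the
#' canonical registry: counts, total areas and mean areas per distance bin x
#' subtype and per area bin x subtype, joint distance x area bin counts and
#' total areas, plus the case's total tumor area and mean tumor area per
#' slide. Mean-area entries are 0 where the count is 0.
#'
#' @param components list of `tls_component` (all slides of the case).
#' @param heatmaps list of post-processed `tissue_heatmap` for the case.
#' @return Named numeric vector of length 226 with attribute
#'   `registry_version`.
#' @export
build_spatial_features <- function(components, heatmaps) {
  stopifnot(length(heatmaps) >= 1L)
  reg <- spatial_feature_registry()
  v <- structure(numeric(length(reg)), names = reg)

  if (length(components)) {
    sub <- vapply(components, function(x) as.integer(x$subtype), 0L)
    area <- vapply(components, function(x) x$area_mm2, 0)
    dist <- vapply(components, function(x) x$signed_margin_distance_mm, 0)
    stopifnot(all(is.finite(dist)), all(area > 0))
    db <- bin_distance(dist) + 1L
    ab <- bin_area(area) + 1L
    for (i in seq_along(components)) {
      dl <- DIST_BIN_LABELS[db[i]]; al <- AREA_BIN_LABELS[ab[i]]
      sl <- SUBTYPE_LABELS[sub[i]]
      k <- paste0("dist_", dl, "_", sl)
      v[paste0(k, "_count")] <- v[paste0(k, "_count")] + 1
      v[paste0(k, "_total_area")] <- v[paste0(k, "_total_area")] + area[i]
      k <- paste0("area_", al, "_", sl)
      v[paste0(k, "_count")] <- v[paste0(k, "_count")] + 1
      v[paste0(k, "_total_area")] <- v[paste0(k, "_total_area")] + area[i]
      k <- paste0("joint_", dl, "_", al)
      v[paste0(k, "_count")] <- v[paste0(k, "_count")] + 1
      v[paste0(k, "_total_area")] <- v[paste0(k, "_total_area")] + area[i]
    }
    # mean areas: total / count where count > 0
    for (prefix in c(paste0("dist_", rep(DIST_BIN_LABELS, each = 3), "_",
                            SUBTYPE_LABELS),
                     paste0("area_", rep(AREA_BIN_LABELS, each = 3), "_",
                            SUBTYPE_LABELS))) {
      n <- v[paste0(prefix, "_count")]
      if (n > 0) v[paste0(prefix, "_mean_area")] <-
          v[paste0(prefix, "_total_area")] / n
    }
  }

  tumor_area <- sum(vapply(heatmaps, function(h) {
    validate_heatmap(h)
    sum(h$labels == 2L) * h$pixel_pitch_mm^2
  }, 0))
  v["tumor_total_area_mm2"] <- tumor_area
  v["tumor_mean_area_per_slide_mm2"] <- tumor_area / length(heatmaps)
  attr(v, "registry_version") <- attr(reg, "registry_version")
  v
}

#' Case-level spatial features straight from raw heatmaps
#'
#' Convenience wrapper: post-processes each slide heatmap, extracts TLS
#' components and builds the 226-entry feature vector.
#'
#' @param heatmaps list of raw `tissue_heatmap` for one case.
#' @param min_tumor_px post-processing tumor size threshold (default 20).
#' @param clean whether to post-process first (default TRUE).
#' @return Named numeric vector of length 226.
#' @export
case_spatial_features <- function(heatmaps, min_tumor_px = 20L,
                                  clean = TRUE) {
  if (clean)
    heatmaps <- lapply(heatmaps, postprocess, min_tumor_px = min_tumor_px)
  comps <- unlist(lapply(heatmaps, tls_components), recursive = FALSE)
  build_spatial_features(comps, heatmaps)
}
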