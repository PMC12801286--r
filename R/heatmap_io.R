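#' Read and write tissue heatmaps
#'
#' A heatmap is stored as two single-channel label images
#' (`<prefix>_labels.png`, `<prefix>_subtypes.png`; 8-bit, label value =
#' pixel value) plus a sidecar JSON `<prefix>.json` carrying `slide_id` and
#' `pixel_pitch_mm`. TIFF output is available when the `tiff` package is
#' installed. A plain-text grid format (whitespace-separated integers, one
#' grid row per line) is supported for small fixtures.
#'
#' @param h a `tissue_heatmap`.
#' @param prefix path prefix (no extension).
#' @param format `"png"` or `"tiff"`.
#' @return `write_heatmap` returns the prefix invisibly; `read_heatmap`
#'   returns a `tissue_heatmap`.
#' @export
write_heatmap <- function(h, prefix, format = c("png", "tiff")) {
  validate_heatmap(h)
  format <- match.arg(format)
  if (format == "png") {
    png::writePNG(h$labels / 255, paste0(prefix, "_labels.png"))
    png::writePNG(h$subtypes / 255, paste0(prefix, "_subtypes.png"))
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF output")
    tiff::writeTIFF(h$labels / 255, paste0(prefix, "_labels.tif"),
                    bits.per.sample = 8L)
    tiff::writeTIFF(h$subtypes / 255, paste0(prefix, "_subtypes.tif"),
                    bits.per.sample = 8L)
  }
  jsonlite::write_json(list(slide_id = h$slide_id,
                            pixel_pitch_mm = h$pixel_pitch_mm),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_heatmap
#' @export
read_heatmap <- function(prefix, format = c("png", "tiff")) {
  format <- match.arg(format)
  read1 <- function(path) {
    img <- if (format == "png") png::readPNG(path) else tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  }
  ext <- if (format == "png") ".png" else ".tif"
  labels <- read1(paste0(prefix, "_labels", ext))
  subtypes <- read1(paste0(prefix, "_subtypes", ext))
  meta <- jsonlite::read_json(paste0(prefix, ".json"))
  tissue_heatmap(labels, subtypes,
                 pixel_pitch_mm = meta$pixel_pitch_mm,
                 slide_id = meta$slide_id)
}

#' @rdname write_heatmap
#' @param labels_file,subtypes_file plain-text grid files; `subtypes_file`
#'   may be `NULL` (TLS pixels default to Agg).
#' @param pixel_pitch_mm,slide_id metadata for the text reader.
#' @export
read_heatmap_text <- function(labels_file, subtypes_file = NULL,
                              pixel_pitch_mm = 0.064, slide_id = "slide") {
  read_grid <- function(path) {
    rows <- lapply(readLines(path), function(x)
      as.integer(strsplit(trimws(x), "\\s+")[[1]]))
    rows <- rows[lengths(rows) > 0L]
    do.call(rbind, rows)
  }
  labels <- read_grid(labels_file)
  subtypes <- if (!is.null(subtypes_file)) read_grid(subtypes_file) else NULL
  tissue_heatmap(labels, subtypes, pixel_pitch_mm = pixel_pitch_mm,
                 slide_id = slide_id)
}
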