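#' Annotated ultrasound image
#'
#' Container for an 8-bit RGB colour Doppler still image on which the nodule
#' has been manually outlined in a single solid annotation colour. Pixels are
#' stored as an integer array `height x width x 3` (row-major, origin top
#' left, 0-based geometry semantics: all distances are between pixel centres).
#'
#' @param pixels integer array `h x w x 3`, each channel in 0..255.
#' @param annotation_color length-3 integer RGB triple of the manual outline.
#'   Defaults to pure green `(0, 255, 0)`: grey-scale tissue has R = G = B and
#'   standard Doppler colour maps occupy red/yellow and blue/cyan hues, so
#'   pure green cannot collide with either.
#' @param id optional image identifier (used by [select_representative_image()]).
#' @return an object of class `annotated_image`.
#' @export
annotated_image <- function(pixels, annotation_color = c(0L, 255L, 0L),
                            id = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_vicad("`pixels` must be an h x w x 3 array", "vicad_format_error")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop_vicad("image must be at least 1 x 1", "vicad_format_error")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_vicad("pixel channels must lie in [0, 255]", "vicad_format_error")
  annotation_color <- as.integer(annotation_color)
  if (length(annotation_color) != 3L || anyNA(annotation_color) ||
      any(annotation_color < 0L | annotation_color > 255L))
    stop_vicad("`annotation_color` must be an RGB triple in 0..255",
               "vicad_validation_error")
  structure(list(pixels = array(as.integer(round(pixels)), dim(pixels)),
                 height = dim(pixels)[1], width = dim(pixels)[2],
                 annotation_color = annotation_color, id = id),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image> %d x %d px, outline colour (%s)%s\n",
              x$height, x$width, paste(x$annotation_color, collapse = ","),
              if (is.null(x$id)) "" else paste0(", id ", x$id)))
  invisible(x)
}

# decode a PNG/TIFF into an h x w x 3 integer array in 0..255
decode_raster <- function(path) {
  if (!file.exists(path))
    stop_vicad(sprintf("file not found: %s", path), "vicad_io_error")
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop_vicad(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext),
               "vicad_format_error")),
    error = function(e) {
      if (inherits(e, "vicad_error")) stop(e)
      stop_vicad(sprintf("cannot decode '%s': %s", path, conditionMessage(e)),
                 "vicad_format_error")
    })
  if (is.matrix(raw)) raw <- array(raw, c(dim(raw), 1L))
  nch <- dim(raw)[3]
  rgb <- if (nch >= 3L) raw[, , 1:3, drop = FALSE]
         else array(raw[, , 1L], c(dim(raw)[1:2], 3L))  # grey -> RGB
  array(as.integer(round(rgb * 255)), dim(rgb))
}

#' Read an annotated colour Doppler image
#'
#' Reads a lossless 8-bit image (PNG or TIFF) without resampling or colour
#' conversion beyond forcing three channels. Lossy formats are deliberately
#' unsupported: outline recovery and grey-pixel elimination both rely on exact
#' channel values, which JPEG-type compression destroys.
#'
#' @inheritParams annotated_image
#' @param path path to a PNG or TIFF file.
#' @return an [annotated_image()].
#' @export
read_annotated_image <- function(path, annotation_color = c(0L, 255L, 0L),
                                 id = NULL) {
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  annotated_image(decode_raster(path), annotation_color, id = id)
}

#' Write an annotated image losslessly
#'
#' @param image an [annotated_image()].
#' @param path output path; extension selects PNG or TIFF.
#' @return `path`, invisibly.
#' @export
write_annotated_image <- function(image, path) {
  stopifnot(inherits(image, "annotated_image"))
  arr <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, path),
    tif = , tiff = tiff::writeTIFF(arr, path, compression = "none"),
    stop_vicad(sprintf("unsupported output format '.%s'", ext),
               "vicad_format_error"))
  invisible(path)
}

# 4-connected labelling of the complement of `barrier`; returns the logical
# matrix of pixels reachable from the image border without crossing a barrier
# pixel. An 8-connected closed barrier curve blocks every 4-connected path
# (digital Jordan property), which is what makes a 1 px hand-drawn outline a
# watertight fence here.
flood_outside <- function(barrier) {
  lab <- EBImage::bwlabel(!barrier)        # EBImage labels 4-connected sets
  h <- nrow(barrier); w <- ncol(barrier)
  border <- c(lab[1, ], lab[h, ], lab[, 1], lab[, w])
  border_labels <- setdiff(unique(border), 0)
  matrix(lab %in% border_labels, h, w)
}

#' Recover the primary ROI from a manual outline
#'
#' Extracts the filled interior of the hand-drawn closed outline: the
#' background is flood-filled from every border pixel with outline pixels
#' acting as barriers, and the interior is whatever remains. Outline pixels
#' themselves are excluded from the mask; enclosed background islands are
#' filled so the primary ROI is simply connected (the nodule is a solid
#' region and the VI is computed over its whole area).
#'
#' @param image an [annotated_image()]; the outline must be drawn in
#'   `image$annotation_color` (exact channel match, no tolerance).
#' @param select_largest if several disjoint closed outlines are present,
#'   `TRUE` keeps the largest interior instead of raising an ambiguity error.
#' @return logical matrix, `TRUE` inside the nodule.
#' @export
extract_roi_from_outline <- function(image, select_largest = FALSE) {
  stopifnot(inherits(image, "annotated_image"))
  px <- image$pixels; ac <- image$annotation_color
  outline <- px[, , 1] == ac[1] & px[, , 2] == ac[2] & px[, , 3] == ac[3]
  if (!any(outline))
    stop_vicad("no pixel matches the annotation colour: outline missing",
               "vicad_missing_outline_error")
  outside <- flood_outside(outline)
  enclosed <- !outline & !outside
  if (!any(enclosed))
    stop_vicad(paste("outline is not closed: flood fill from the border",
                     "reaches every non-outline pixel"),
               "vicad_open_contour_error")
  lab <- EBImage::bwlabel(enclosed)
  ncomp <- max(lab)
  if (ncomp > 1L) {
    if (!select_largest)
      stop_vicad(sprintf(paste("found %d disjoint closed outlines; pass",
                               "select_largest = TRUE to keep the largest"),
                         ncomp), "vicad_ambiguous_outline_error")
    sizes <- tabulate(lab[lab > 0], nbins = ncomp)
    lab[lab != which.max(sizes)] <- 0L
  }
  mask <- lab > 0
  # fill enclosed background islands (interior annotation smudges etc.)
  mask <- EBImage::fillHull(mask) > 0 & !outline
  mask
}

#' Read / write a binary ROI mask image
#'
#' Masks are stored as single-channel PNGs, 0 = outside, 255 = inside.
#' Multi-channel mask images are accepted on read and binarized at 50% grey.
#'
#' @param path PNG file path.
#' @return `read_mask`: a logical matrix. `write_mask`: `path`, invisibly.
#' @export
read_mask <- function(path) {
  arr <- decode_raster(path)
  mask <- arr[, , 1] >= 128 & arr[, , 2] >= 128 & arr[, , 3] >= 128
  if (!any(mask))
    stop_vicad("mask is empty (no inside pixels)", "vicad_validation_error")
  mask
}

#' @rdname read_mask
#' @param mask logical matrix, `TRUE` inside.
#' @export
write_mask <- function(mask, path) {
  mask <- assert_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read / write a cohort table
#'
#' Comma-separated, one row per nodule. Canonical columns: `nodule_id`,
#' `malignant` (0/1), `overall_vi`, then `peripheral_vi_<n>` and
#' `central_vi_<n>` per offset level n, then the four binary grey-scale
#' ultrasound features `gsu_microcalc`, `gsu_hypoechoic`, `gsu_irregular`,
#' `gsu_tall`.
#'
#' @param path CSV file path.
#' @return `read_cohort`: a data frame. `write_cohort`: `path`, invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop_vicad(sprintf("file not found: %s", path), "vicad_io_error")
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("nodule_id", "malignant")
  if (!all(need %in% names(df)))
    stop_vicad(sprintf("cohort table must contain columns: %s",
                       paste(need, collapse = ", ")), "vicad_schema_error")
  df$malignant <- df$malignant != 0
  df
}

#' @rdname read_cohort
#' @param cohort data frame in the cohort schema.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (nm in names(out)) if (is.logical(out[[nm]])) out[[nm]] <- as.integer(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
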