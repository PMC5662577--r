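#' Extract colour-coded flow pixels
#'
#' Colour Doppler overlays flow information as coloured pixels on a grey-scale
#' image; grey-scale tissue pixels have (nearly) equal channels. A pixel inside
#' the ROI is classified as colour iff its channel spread
#' `max(R,G,B) - min(R,G,B)` exceeds `tau`. The default `tau = 0` is the
#' literal complement of "grey" and is correct for lossless inputs; for images
#' that passed through a lossy pipeline a spread threshold of 10–20 absorbs
#' chroma noise.
#'
#' @param image an [annotated_image()].
#' @param mask logical matrix, the region of interest.
#' @param tau non-negative channel-spread threshold (default 0).
#' @return an object of class `color_mask`: logical matrix (`TRUE` = colour
#'   flow pixel, always `FALSE` outside `mask`) with attribute
#'   `spread_threshold`.
#' @export
classify_color_pixels <- function(image, mask, tau = 0) {
  stopifnot(inherits(image, "annotated_image"))
  mask <- assert_mask(mask, allow_empty = TRUE)
  if (!identical(dim(mask), dim(image$pixels)[1:2]))
    stop_vicad("mask and image dimensions differ", "vicad_validation_error")
  if (tau < 0)
    stop_vicad("`tau` must be >= 0", "vicad_validation_error")
  px <- image$pixels
  spread <- pmax(px[, , 1], px[, , 2], px[, , 3]) -
            pmin(px[, , 1], px[, , 2], px[, , 3])
  structure(spread > tau & mask, spread_threshold = tau,
            class = c("color_mask", "matrix"))
}

#' Vascular index of a region
#'
#' The vascular index (VI) is the percentage of colour-coded flow pixels among
#' all pixels of a region. The VI of an empty region is undefined and raises
#' an error; cohort code represents it as missing (never as 0, which would
#' bias group statistics downwards).
#'
#' @param color logical matrix of colour pixels (see [classify_color_pixels()]).
#' @param region logical matrix, the region to score.
#' @return VI in percent.
#' @export
vascular_index <- function(color, region) {
  region <- assert_mask(region, allow_empty = TRUE)
  if (!any(region))
    stop_vicad("vascular index of an empty region is undefined",
               "vicad_empty_region_error")
  100 * sum(color & region) / sum(region)
}

#' Overall and regional vascular profile of one nodule
#'
#' Runs the full per-image pipeline: partitions the ROI at `offset_pct` (see
#' [inward_offset()]), classifies colour pixels once over the primary ROI, and
#' computes overall, peripheral and central VI. The colour-pixel counts are
#' conserved exactly: overall count = peripheral count + central count, so the
#' overall VI is the area-weighted mean of the regional VIs.
#'
#' @inheritParams classify_color_pixels
#' @param offset_pct offset level in percent of the maximum diameter.
#' @param mode offsetting mode, see [inward_offset()].
#' @return an object of class `vascular_profile`: list with `overall_vi`,
#'   `peripheral_vi`, `central_vi` (percent; `NA` for an empty region),
#'   `offset_pct`, areas, colour-pixel counts and `source_image_id`.
#' @export
profile_nodule <- function(image, mask, offset_pct = 22, tau = 0,
                           mode = c("erosion", "distance")) {
  mask <- assert_mask(mask)
  mode <- match.arg(mode)
  part <- inward_offset(mask, offset_pct, mode)
  color <- classify_color_pixels(image, mask, tau)
  vi_or_na <- function(region)
    if (any(region)) vascular_index(color, region) else NA_real_
  structure(list(
    overall_vi    = vascular_index(color, mask),
    peripheral_vi = vi_or_na(part$peripheral),
    central_vi    = vi_or_na(part$central),
    offset_pct = offset_pct, offset_px = part$offset_px, mode = mode,
    roi_area_px = sum(mask), central_area_px = sum(part$central),
    peripheral_area_px = sum(part$peripheral),
    color_px_total = sum(color & mask),
    source_image_id = image$id), class = "vascular_profile")
}

#' @export
print.vascular_profile <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", v)
  cat(sprintf(paste0("<vascular_profile> image %s, offset %g%%: overall %s, ",
                     "peripheral %s, central %s\n"),
              if (is.null(x$source_image_id)) "?" else x$source_image_id,
              x$offset_pct, fmt(x$overall_vi), fmt(x$peripheral_vi),
              fmt(x$central_vi)))
  invisible(x)
}

#' Select the representative image of a nodule
#'
#' When several colour Doppler stills of the same nodule are available, the
#' image with the highest overall VI is taken forward to regional analysis
#' (selection uses the whole-nodule VI, which is offset-independent). Ties go
#' to the earliest image in acquisition order.
#'
#' @param profiles non-empty list of `vascular_profile`s of one nodule.
#' @return the selected `vascular_profile`.
#' @export
select_representative_image <- function(profiles) {
  if (length(profiles) == 0)
    stop_vicad("`profiles` must not be empty", "vicad_validation_error")
  vis <- vapply(profiles, function(p) p$overall_vi, numeric(1))
  if (anyNA(vis))
    stop_vicad("every profile needs an overall VI", "vicad_validation_error")
  profiles[[which.max(vis)]]  # which.max keeps the first maximum
}

#' Per-nodule output row for the VI CSV
#'
#' @param profile a `vascular_profile`.
#' @param nodule_id nodule identifier.
#' @return one-row data frame in the per-nodule CSV schema.
#' @export
profile_row <- function(profile, nodule_id) {
  data.frame(nodule_id = nodule_id,
             image_id = if (is.null(profile$source_image_id)) NA_character_
                        else profile$source_image_id,
             offset_pct = profile$offset_pct,
             overall_vi = profile$overall_vi,
             peripheral_vi = profile$peripheral_vi,
             central_vi = profile$central_vi,
             roi_area_px = profile$roi_area_px,
             central_area_px = profile$central_area_px,
             color_px_total = profile$color_px_total,
             stringsAsFactors = FALSE)
}
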