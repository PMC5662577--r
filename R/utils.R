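#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when realizing offset distances in
#' pixels, reconstructing confusion counts from published rates, and formatting
#' report percentages to one decimal. Base R's `round()` rounds half to even,
#' which would turn e.g. 56.25 into 56.2 rather than 56.3.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(56.25, 1) # 56.3
#' round_half_up(2.5)      # 3
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values that are exactly .5 after the
  # multiply do not fall victim to binary representation just below .5
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

stop_vicad <- function(msg, class, ...) {
  stop(structure(class = c(class, "vicad_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

is_binary_matrix <- function(m) {
  is.matrix(m) && (is.logical(m) || all(m %in% c(0, 1)))
}

assert_mask <- function(mask, allow_empty = FALSE, arg = "mask") {
  if (!is_binary_matrix(mask))
    stop_vicad(sprintf("`%s` must be a logical (or 0/1) matrix", arg),
               "vicad_validation_error")
  mask <- mask != 0
  if (!allow_empty && !any(mask))
    stop_vicad(sprintf("`%s` contains no foreground pixels", arg),
               "vicad_validation_error")
  mask
}

# logical matrix -> n x 2 matrix of (row, col) pixel-centre coordinates
mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)
}
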