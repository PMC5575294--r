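#' Average repeated gain (flat) exposures
#'
#' Pixelwise arithmetic mean of repeated sample-free exposures; averaging n
#' frames reduces the detector read noise on the flat by sqrt(n).
#'
#' @param gain_frames list of numeric matrices of identical dimension.
#' @return a numeric matrix, the pixelwise mean.
#' @export
average_gain <- function(gain_frames) {
  if (!is.list(gain_frames) || length(gain_frames) == 0) {
    stop("gain_frames must be a non-empty list of matrices")
  }
  dims <- dim(gain_frames[[1]])
  ok <- vapply(gain_frames, function(f) is.matrix(f) && all(dim(f) == dims),
               TRUE)
  if (!all(ok)) stop("all gain frames must share the same dimensions")
  Reduce(`+`, gain_frames) / length(gain_frames)
}

#' Flat-field calibration set
#'
#' Bundles the averaged gain (sample-free) and offset (beam-off) images used
#' for flat-field correction. Lists of repeated exposures are averaged with
#' [average_gain()].
#'
#' @param gain a matrix or list of matrices (sample-free exposures).
#' @param offset a matrix or list of matrices (no-beam exposures).
#' @return An object of class `"flat_field_set"` with elements `gain`,
#'   `offset` and `n_gain_averaged`. A warning is emitted if the gain does
#'   not exceed the offset everywhere (unusable pixels will be masked).
#' @export
flat_field_set <- function(gain, offset) {
  n_gain <- 1L
  if (is.list(gain)) { n_gain <- length(gain); gain <- average_gain(gain) }
  if (is.list(offset)) offset <- average_gain(offset)
  stopifnot(is.matrix(gain), is.matrix(offset), all(dim(gain) == dim(offset)))
  if (any(gain <= offset, na.rm = TRUE)) {
    warning("gain does not exceed offset at every pixel; ",
            "those pixels will be masked in corrected images")
  }
  structure(list(gain = gain, offset = offset, n_gain_averaged = n_gain),
            class = "flat_field_set")
}

#' Flat-field correction of a radiograph
#'
#' Normalizes an object image by the detector's fixed-pattern response:
#' `FFC = (object - offset) / (gain - offset)`, yielding the transmission
#' of the sample in `[0, 1]` (up to noise). Pixels where the gain does not
#' exceed the offset are masked (`NA`) rather than left infinite.
#'
#' @param object_img numeric matrix, raw object image (counts).
#' @param flat a [flat_field_set()].
#' @return transmission matrix; masked pixels are `NA`.
#' @export
flat_field_correct <- function(object_img, flat) {
  stopifnot(inherits(flat, "flat_field_set"), is.matrix(object_img),
            all(dim(object_img) == dim(flat$gain)))
  denom <- flat$gain - flat$offset
  out <- (object_img - flat$offset) / denom
  out[denom <= 0] <- NA_real_
  out
}

#' Material thickness from transmission via the Beer-Lambert law
#'
#' Inverts `I = I0 exp(-mu x)`: `x = -log(transmission) / mu`, pixelwise.
#' Non-positive transmissions (unphysical, e.g. masked or dead pixels) are
#' masked; transmissions slightly above 1 (noise) give small negative
#' thicknesses and are kept, so that downstream statistics stay unbiased.
#'
#' @param transmission numeric matrix of transmissions.
#' @param mu_abs linear absorption coefficient, 1/mm (> 0).
#' @return thickness matrix in mm; masked pixels are `NA`.
#' @export
beer_lambert_thickness <- function(transmission, mu_abs) {
  if (mu_abs <= 0) stop("mu_abs must be > 0")
  transmission[!is.na(transmission) & transmission <= 0] <- NA_real_
  -log(transmission) / mu_abs
}
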