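#' Standard regions of interest around the needle and first fronts
#'
#' Builds the three square ROIs used for heterogeneity analysis: `SC`
#' centred at the needle tip, and `SWF_h` / `SWF_v` centred at the first
#' post-onset wetting-front positions along the horizontal (rightward) and
#' vertical (downward) axes.
#'
#' @param needle_tip `c(row, col)` needle-tip pixel.
#' @param trace a [wf_trace()] with at least one post-onset sample
#'   (finite, positive front).
#' @param dims frame dimensions `c(nrow, ncol)`.
#' @param pixel_size pixel pitch, um.
#' @param size_mm ROI side, mm (default 0.9; 100 px at 9 um).
#' @return named list (`SC`, `SWF_h`, `SWF_v`) of ROIs, each a list with
#'   `rows = c(first, last)`, `cols = c(first, last)` and `center`. ROIs
#'   extending beyond the frame are clipped with a warning.
#' @export
define_rois <- function(needle_tip, trace, dims, pixel_size = 9,
                        size_mm = 0.9) {
  first <- which(is.finite(trace$wf_h) & trace$wf_h > 0 &
                 is.finite(trace$wf_v) & trace$wf_v > 0)[1]
  if (is.na(first)) stop("trace has no post-onset sample with both fronts")
  size_px <- max(1L, round(size_mm * 1000 / pixel_size))
  half <- size_px %/% 2
  px_mm <- pixel_size / 1000
  centers <- list(
    SC    = needle_tip,
    SWF_h = c(needle_tip[1], needle_tip[2] + trace$wf_h[first] / px_mm),
    SWF_v = c(needle_tip[1] + trace$wf_v[first] / px_mm, needle_tip[2])
  )
  clipped <- FALSE
  rois <- lapply(centers, function(ct) {
    ct <- round(ct)
    rows <- c(ct[1] - half, ct[1] + half)
    cols <- c(ct[2] - half, ct[2] + half)
    if (rows[1] < 1 || rows[2] > dims[1] || cols[1] < 1 ||
        cols[2] > dims[2]) {
      clipped <<- TRUE
      rows <- pmin(pmax(rows, 1), dims[1])
      cols <- pmin(pmax(cols, 1), dims[2])
    }
    list(rows = rows, cols = cols, center = ct)
  })
  if (clipped) warning("ROI(s) clipped to frame bounds")
  rois
}

#' Coefficient of variation of ROI intensities over time
#'
#' Per-frame mean, standard deviation and coefficient of variation
#' `C_v = sigma / mu` of the pixel values inside each ROI. `C_v` tracks the
#' heterogeneity of local solution content: it drops as solution spreads
#' into the surrounding tissue. The population (n-denominator) standard
#' deviation is used.
#'
#' @param stack an [image_stack()] (any pixel scale: counts, transmission
#'   or RCS).
#' @param rois a single ROI (list with `rows`, `cols`) or a named list of
#'   ROIs as from [define_rois()].
#' @return data frame with `roi`, `time`, `mean`, `sd`, `cv`; `cv` is `NA`
#'   where the ROI mean is 0.
#' @export
roi_cv <- function(stack, rois) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.null(rois$rows)) rois <- list(ROI = rois)
  dims <- dim(stack$frames[[1]])
  out <- lapply(names(rois), function(nm) {
    roi <- rois[[nm]]
    if (roi$rows[1] < 1 || roi$rows[2] > dims[1] ||
        roi$cols[1] < 1 || roi$cols[2] > dims[2]) {
      stop("ROI ", nm, " outside frame")
    }
    stats <- t(vapply(stack$frames, function(f) {
      v <- f[roi$rows[1]:roi$rows[2], roi$cols[1]:roi$cols[2]]
      v <- v[is.finite(v)]
      mu <- mean(v)
      sg <- sqrt(mean((v - mu)^2))   # population sigma
      c(mu, sg, if (mu == 0) NA_real_ else sg / mu)
    }, numeric(3)))
    data.frame(roi = nm, time = stack$timestamps,
               mean = stats[, 1], sd = stats[, 2], cv = stats[, 3])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
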