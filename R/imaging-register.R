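# Integer translation of a matrix, vacated pixels filled with `fill`.
translate_frame <- function(m, dr, dc, fill = NA_real_) {
  dr <- as.integer(round(dr)); dc <- as.integer(round(dc))
  out <- matrix(fill, nrow(m), ncol(m))
  r_src <- seq_len(nrow(m)) - dr
  c_src <- seq_len(ncol(m)) - dc
  r_ok <- r_src >= 1 & r_src <= nrow(m)
  c_ok <- c_src >= 1 & c_src <= ncol(m)
  out[r_ok, c_ok] <- m[r_src[r_ok], c_src[c_ok]]
  out
}

# FFT cross-correlation shift of frame relative to ref (integer pixels).
# Positive (dr, dc): frame content moved down/right relative to ref.
xcorr_shift <- function(ref, frame, mask = NULL) {
  a <- ref; b <- frame
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  if (!is.null(mask)) { a[mask] <- 0; b[mask] <- 0 }
  a <- a - mean(a); b <- b - mean(b)
  if (all(a == 0) || all(b == 0)) return(c(NA_real_, NA_real_))
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE))
  idx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) { s <- i - 1; if (s > n / 2) s - n else s }
  c(wrap(idx[1], nrow(a)), wrap(idx[2], ncol(a)))
}

#' Register a stack against a reference frame (drift compensation)
#'
#' Estimates the integer-pixel translation of each frame relative to a
#' reference frame by maximizing the (mean-subtracted) cross-correlation,
#' then shifts each frame back so the sample is stationary. Intended to
#' compensate slow sample drift during long exposures; subpixel accuracy is
#' not attempted. An optional mask (e.g. the needle region, which is
#' stationary in the lab frame while the sample drifts) excludes pixels
#' from the similarity score.
#'
#' @param stack an [image_stack()].
#' @param reference_index frame used as the reference (default 1).
#' @param mask optional logical matrix, `TRUE` for pixels to ignore.
#' @return list with `shifts` (n x 2 matrix of `(dr, dc)` per frame) and
#'   `corrected` (the re-aligned [image_stack()]; vacated borders are `NA`).
#'   Featureless (constant) frames get zero shift with a warning.
#' @export
register_drift <- function(stack, reference_index = 1, mask = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  n <- length(stack$frames)
  if (n < 2) stop("need at least 2 frames to register")
  ref <- stack$frames[[reference_index]]
  shifts <- matrix(0, n, 2, dimnames = list(NULL, c("dr", "dc")))
  corrected <- stack$frames
  warned <- FALSE
  for (i in seq_len(n)) {
    if (i == reference_index) next
    s <- xcorr_shift(ref, stack$frames[[i]], mask)
    if (anyNA(s)) {
      warned <- TRUE
      s <- c(0, 0)
    }
    shifts[i, ] <- s
    if (any(s != 0)) {
      corrected[[i]] <- translate_frame(stack$frames[[i]], -s[1], -s[2])
    }
  }
  if (warned) warning("featureless frame(s); zero shift assumed")
  list(shifts = shifts,
       corrected = image_stack(corrected, stack$timestamps,
                               pixel_size = stack$pixel_size,
                               exposure = stack$exposure))
}
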