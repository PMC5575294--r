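#' Time-ordered stack of radiograph frames
#'
#' Container for a time-lapse series of 2D detector images with the
#' acquisition geometry needed downstream: pixel size and timestamps.
#' Frames are base R numeric matrices in detector counts (row 1 at the top
#' of the image); masked/invalid pixels are `NA`.
#'
#' @param frames list of numeric matrices, all the same dimension.
#' @param timestamps numeric vector of acquisition times, s, strictly
#'   increasing, one per frame.
#' @param pixel_size pixel pitch, um (default 9).
#' @param exposure exposure time per frame, s (default 1).
#' @return An object of class `"image_stack"`.
#' @export
image_stack <- function(frames, timestamps, pixel_size = 9, exposure = 1) {
  stopifnot(is.list(frames), length(frames) >= 1)
  dims <- dim(frames[[1]])
  if (is.null(dims)) stop("frames must be matrices")
  ok <- vapply(frames, function(f) is.matrix(f) && all(dim(f) == dims), TRUE)
  if (!all(ok)) stop("all frames must share the same dimensions")
  if (length(timestamps) != length(frames)) {
    stop("one timestamp per frame required")
  }
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(
    frames = frames,
    timestamps = as.numeric(timestamps),
    pixel_size = pixel_size,   # um
    exposure = exposure        # s
  ), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Radiograph stack: %d frames of %d x %d px (%.3g x %.3g mm)\n",
              length(x$frames), d[1], d[2],
              d[2] * x$pixel_size / 1000, d[1] * x$pixel_size / 1000))
  cat(sprintf("  pixel size %g um, t = %g .. %g s\n", x$pixel_size,
              min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' Write a radiograph stack to a directory of TIFF files
#'
#' One 16-bit grayscale TIFF per frame (`frame_0001.tif`, ...) plus a
#' plain-text YAML sidecar `stack.yml` holding pixel size, exposure and
#' timestamps. Counts are clamped to `[0, 65535]` and rounded; the round
#' trip is lossless for integer counts in range.
#'
#' @param stack an [image_stack()].
#' @param path directory to write into (created if needed).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(stack$frames)) {
    f <- stack$frames[[i]]
    f[is.na(f)] <- 0
    f <- pmin(pmax(round(f), 0), .DEPOT_MAX_COUNT)
    tiff::writeTIFF(f / .DEPOT_MAX_COUNT,
                    file.path(path, sprintf("frame_%04d.tif", i)),
                    bits.per.sample = 16)
  }
  meta <- list(pixel_size_um = stack$pixel_size,
               exposure_s = stack$exposure,
               n_frames = length(stack$frames),
               timestamps_s = as.numeric(stack$timestamps))
  yaml::write_yaml(meta, file.path(path, "stack.yml"))
  invisible(path)
}

#' Read a radiograph stack written by [write_stack()]
#'
#' Reads `frame_*.tif` files in name order plus the `stack.yml` sidecar.
#' If the sidecar is missing, defaults (9 um pixels, 1 s exposure, frame
#' index as timestamp) are applied with a warning.
#'
#' @param path directory containing the stack.
#' @return an [image_stack()].
#' @export
read_stack <- function(path) {
  if (!dir.exists(path)) stop("stack directory not found: ", path)
  files <- sort(list.files(path, pattern = "^frame_\\d+\\.tif$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no frame_*.tif files in ", path)
  frames <- lapply(files, function(f) {
    img <- tryCatch(tiff::readTIFF(f), error = function(e) {
      stop("malformed TIFF file ", f, ": ", conditionMessage(e))
    })
    if (length(dim(img)) == 3) img <- img[, , 1]  # tolerate grayscale-as-RGB
    round(img * .DEPOT_MAX_COUNT)
  })
  meta_file <- file.path(path, "stack.yml")
  if (file.exists(meta_file)) {
    meta <- yaml::read_yaml(meta_file)
    ts <- as.numeric(meta$timestamps_s)
    px <- meta$pixel_size_um
    ex <- meta$exposure_s
    if (is.null(ts) || length(ts) != length(frames)) {
      warning("sidecar timestamps missing/mismatched; using frame index")
      ts <- seq_along(frames) - 1
    }
    if (is.null(px)) { warning("pixel size missing; default 9 um"); px <- 9 }
    if (is.null(ex)) ex <- 1
  } else {
    warning("stack.yml sidecar missing; applying defaults ",
            "(9 um pixels, frame index timestamps)")
    ts <- seq_along(frames) - 1
    px <- 9
    ex <- 1
  }
  image_stack(frames, ts, pixel_size = px, exposure = ex)
}
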