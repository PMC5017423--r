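# Image stack container and multi-page TIFF IO.

#' Image stack
#'
#' A time-lapse stack: a list of equally sized H x W grayscale frames with
#' intensities in `[0, 1]`, plus pixel size and frame rate metadata.
#'
#' @param frames List of numeric matrices (one per frame).
#' @param pixel_size_um Microns per pixel.
#' @param frame_rate_fps Frames per second.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size_um, frame_rate_fps) {
  if (!is.list(frames) || length(frames) < 1L) {
    pb_stop("`frames` must be a non-empty list of matrices",
            "pillarbeat_format_error")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    pb_stop("all frames must share the same dimensions",
            "pillarbeat_format_error")
  }
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  check_positive_scalar(frame_rate_fps, "frame_rate_fps")
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_rate_fps = frame_rate_fps),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "Image stack: %d frames of %d x %d px, %.4g um/px, %.4g fps (%.2f s)\n",
    length(x$frames), d[1], d[2], x$pixel_size_um, x$frame_rate_fps,
    length(x$frames) / x$frame_rate_fps))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' Read a multi-page TIFF stack
#'
#' Frames are returned as grayscale matrices in `[0, 1]`. RGB pages are
#' converted to luminance with a warning. Pixel size and frame rate come
#' from the arguments (a config value wins over any TIFF metadata, which
#' plain grayscale TIFFs rarely carry).
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_um Microns per pixel.
#' @param frame_rate_fps Frames per second.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size_um, frame_rate_fps) {
  if (!file.exists(path)) {
    pb_stop(sprintf("no such file: %s", path), "pillarbeat_format_error")
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) {
                      pb_stop(sprintf("cannot read TIFF '%s': %s",
                                      path, conditionMessage(e)),
                              "pillarbeat_format_error")
                    })
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(seq_along(pages), function(i) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3L) {
      pb_warn(sprintf("page %d is RGB; converting to grayscale mean", i),
              "pillarbeat_rgb_input")
      pg <- (pg[, , 1] + pg[, , 2] + pg[, , 3]) / 3
    }
    pg
  })
  image_stack(frames, pixel_size_um, frame_rate_fps)
}

#' Write an image stack as a 16-bit multi-page TIFF
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path) {
  frames <- lapply(stack$frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}
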