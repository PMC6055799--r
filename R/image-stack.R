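#' Create an image stack
#'
#' Minimal container for one or more single-channel 2D frames with physical
#' calibration. Frames are numeric matrices indexed `[row, col]`; coordinates
#' elsewhere in the package are `(x = column, y = row)` in pixels, 1-based.
#'
#' @param frames a numeric matrix (single frame) or list of equally sized
#'   matrices.
#' @param pixel_size_um pixel size in micrometres per pixel.
#' @param frame_interval_s time between consecutive frames in seconds.
#' @return An `image_stack` object.
#' @export
image_stack <- function(frames, pixel_size_um = 0.05, frame_interval_s = 1) {
  if (is.matrix(frames)) frames <- list(frames)
  if (!length(frames) || !all(vapply(frames, is.matrix, TRUE)))
    stop_ernet("frames must be a matrix or a list of matrices")
  dm <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), dm), TRUE)))
    stop_ernet("all frames must share the same dimensions")
  if (pixel_size_um <= 0 || frame_interval_s <= 0)
    stop_ernet("pixel_size_um and frame_interval_s must be positive")
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("image_stack: %d frame(s) of %dx%d px, %.3f um/px, dt = %gs\n",
              length(x$frames), d[1], d[2], x$pixel_size_um,
              x$frame_interval_s))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' Read an image stack from a (multi-page) TIFF file
#'
#' @param path TIFF file path.
#' @inheritParams image_stack
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, pixel_size_um = 0.05,
                             frame_interval_s = 1) {
  if (!file.exists(path)) stop_ernet("file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e)
                      stop_ernet("failed to read TIFF '", path, "': ",
                                 conditionMessage(e)))
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    matrix(as.numeric(p), nrow(p), ncol(p))
  })
  image_stack(frames, pixel_size_um, frame_interval_s)
}

#' Write an image stack to a multi-page TIFF file
#'
#' Intensities are clipped to `[0, 1]` (32-bit float pages are not portable).
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  frames <- lapply(stack$frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a binary mask as an 8-bit TIFF (0/255)
#' @param mask binary matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  mask <- check_mask(mask)
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' Read a binary mask from a TIFF file
#' @param path TIFF file path; any non-zero pixel becomes foreground.
#' @return integer 0/1 matrix.
#' @export
read_mask_tiff <- function(path) {
  s <- read_image_stack(path)
  check_mask(s$frames[[1]] > 0)
}
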