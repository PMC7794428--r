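#' Construct a frame stack
#'
#' A capture is an ordered list of 2-D intensity matrices with a spatial
#' calibration and a frame rate.  Frames are indexed 0-based throughout the
#' package; pixel (row r, col c) has its centre at
#' `((c - 0.5) * mpp, (r - 0.5) * mpp)` um with the origin at the top-left
#' corner and y increasing downward.
#'
#' @param frames list of numeric matrices, all the same shape.
#' @param microns_per_pixel spatial calibration, um/px.
#' @param frame_rate_hz frame rate, Hz.
#' @param load_time,capture_time optional POSIXct timestamps of well loading
#'   and capture start (used by the stale-well check).
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, microns_per_pixel, frame_rate_hz,
                        load_time = NA, capture_time = NA) {
  if (!is.list(frames) || length(frames) == 0)
    stopf("frames must be a non-empty list of matrices")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("all frames must have the same shape")
  if (microns_per_pixel <= 0) stopf("microns_per_pixel must be positive")
  if (frame_rate_hz <= 0) stopf("frame_rate_hz must be positive")
  structure(list(frames = frames,
                 microns_per_pixel = microns_per_pixel,
                 frame_rate_hz = frame_rate_hz,
                 load_time = load_time,
                 capture_time = capture_time),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "frame_stack: %d frames of %d x %d px (%.3g um/px, %.4g Hz, %.3g s)\n",
    length(x$frames), d[1], d[2], x$microns_per_pixel, x$frame_rate_hz,
    length(x$frames) / x$frame_rate_hz))
  invisible(x)
}

#' Field size of a frame stack, um
#' @param stack a [frame_stack()].
#' @return named numeric: `width_um`, `height_um`.
#' @export
stack_field_um <- function(stack) {
  d <- dim(stack$frames[[1]])
  c(width_um = d[2] * stack$microns_per_pixel,
    height_um = d[1] * stack$microns_per_pixel)
}
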