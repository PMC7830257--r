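#' Thermal frame sequence
#'
#' Container for an ordered stack of radiometric temperature frames. Frames
#' are stored as an `H x W x T` numeric array (one matrix per frame along the
#' third dimension) together with the acquisition frame rate and the camera
#' emissivity setting. Emissivity is carried as metadata only; no radiometric
#' correction is applied. All temperatures are degrees Celsius and must lie
#' within the device range -20 to 400 degC; values outside it are rejected.
#'
#' @param frames Numeric `H x W x T` array of temperatures in degC (a matrix
#'   is promoted to a single-frame stack).
#' @param fps Frame rate in frames per second (> 0).
#' @param emissivity Emissivity setting carried as metadata (default 0.95).
#' @return An object of class `thermal_sequence` with elements `frames`,
#'   `fps`, `emissivity` and `units` (fixed `"degC"`).
#' @examples
#' ts <- thermal_sequence(array(25, dim = c(4, 5, 3)), fps = 10)
#' dim(ts$frames)
#' @export
thermal_sequence <- function(frames, fps, emissivity = 0.95) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be an H x W x T array", call. = FALSE)
  if (any(dim(frames) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("`fps` must be a single positive number", call. = FALSE)
  storage.mode(frames) <- "double"
  check_thermal_range(frames)
  structure(
    list(frames = frames, fps = as.numeric(fps),
         emissivity = as.numeric(emissivity), units = "degC"),
    class = "thermal_sequence"
  )
}

# Device range check; reports the first offending frame and pixel.
check_thermal_range <- function(frames) {
  bad <- which(frames < -20 | frames > 400 | !is.finite(frames))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(frames))
    stop(sprintf(
      "temperature %.6g degC outside device range [-20, 400] at frame %d, pixel (row %d, col %d)",
      frames[bad[1L]], idx[3L], idx[1L], idx[2L]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Binary ROI mask sequence
#'
#' Per-frame binary masks aligned to a thermal sequence's pixel grid, stored
#' as an `H x W x T` integer array with values in \{0, 1\}. Masks act as the
#' multiplicative pixel selector when extracting ROI temperatures.
#'
#' @param frames Logical or 0/1 numeric `H x W x T` array (a matrix is
#'   promoted to a single-frame stack).
#' @return An object of class `mask_sequence` with element `frames`.
#' @export
mask_sequence <- function(frames) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be an H x W x T array", call. = FALSE)
  if (is.logical(frames)) {
    storage.mode(frames) <- "integer"
  } else {
    if (!all(frames %in% c(0, 1)))
      stop("mask values must be strictly binary (0 or 1)", call. = FALSE)
    storage.mode(frames) <- "integer"
  }
  structure(list(frames = frames), class = "mask_sequence")
}

#' RGB frame sequence
#'
#' Co-registered RGB frames stored as an `H x W x 3 x T` array of intensities
#' in `[0, 255]`. When paired with a [thermal_sequence()] the frame count and
#' spatial dimensions must match (shared-grid co-registration contract).
#'
#' @param frames Numeric `H x W x 3 x T` array with values in `[0, 255]`.
#' @return An object of class `rgb_sequence` with element `frames`.
#' @export
rgb_sequence <- function(frames) {
  if (!is.array(frames) || length(dim(frames)) != 4L || dim(frames)[3L] != 3L)
    stop("`frames` must be an H x W x 3 x T array", call. = FALSE)
  if (min(frames) < 0 || max(frames) > 255)
    stop("RGB intensities must lie in [0, 255]", call. = FALSE)
  structure(list(frames = frames), class = "rgb_sequence")
}

#' Number of frames in a sequence
#' @param x A `thermal_sequence`, `mask_sequence` or `rgb_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  d <- dim(x$frames)
  as.integer(d[length(d)])
}

#' Frame height and width of a sequence
#' @param x A `thermal_sequence`, `mask_sequence` or `rgb_sequence`.
#' @return Integer vector `c(height, width)`.
#' @export
frame_dim <- function(x) {
  d <- dim(x$frames)
  as.integer(d[1:2])
}

# Shared-grid co-registration check used wherever two sequences are fused.
check_aligned <- function(a, b, what = "sequences") {
  if (n_frames(a) != n_frames(b) ||
      !identical(frame_dim(a), frame_dim(b)))
    stop(sprintf("%s are not aligned: %dx%dx%d vs %dx%dx%d", what,
                 frame_dim(a)[1], frame_dim(a)[2], n_frames(a),
                 frame_dim(b)[1], frame_dim(b)[2], n_frames(b)),
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.thermal_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<thermal_sequence> %d frames of %d x %d at %g fps (%s, emissivity %g)\n",
              d[3], d[1], d[2], x$fps, x$units, x$emissivity))
  cat(sprintf("  range: %.2f .. %.2f degC, %s values\n",
              min(x$frames), max(x$frames),
              format(prod(d), big.mark = ",")))
  invisible(x)
}

#' @export
print.mask_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<mask_sequence> %d frames of %d x %d, %s positive pixels total\n",
              d[3], d[1], d[2], format(sum(x$frames), big.mark = ",")))
  invisible(x)
}
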