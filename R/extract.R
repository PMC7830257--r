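#' Temperatures inside a mask
#'
#' The multiplicative selector at the heart of the pipeline: returns exactly
#' the temperature values at mask-positive pixels of one frame.
#'
#' @param frame Numeric `H x W` temperature matrix.
#' @param mask Binary `H x W` matrix of the same shape.
#' @return Numeric vector of in-mask temperatures (empty if the mask is
#'   empty; the caller decides how to treat an empty ROI).
#' @export
roi_values <- function(frame, mask) {
  if (!identical(dim(frame), dim(mask)))
    stop("frame and mask shapes differ", call. = FALSE)
  frame[mask != 0]
}

#' Aggregate ROI temperatures by one of three statistics
#'
#' The three rival per-frame statistics: `max` (maximum in-mask temperature,
#' degC), `mean` (sum of in-mask temperatures divided by the mask pixel
#' count, degC) and `sum` (the integrated value, degC x pixels). Mean is
#' invariant to the apparent ROI size; sum scales with it — replicating the
#' masked region (two identical nostrils instead of one) doubles the sum and
#' leaves the mean unchanged.
#'
#' @param values Non-empty numeric vector of in-mask temperatures.
#' @param method One of `"mean"`, `"max"`, `"sum"`.
#' @return The aggregated scalar.
#' @export
roi_aggregate <- function(values, method = c("mean", "max", "sum")) {
  method <- match.arg(method)
  if (!length(values))
    stop("empty ROI: no in-mask values to aggregate (missing frame)",
         call. = FALSE)
  switch(method, mean = mean(values), max = max(values), sum = sum(values))
}

new_roi_series <- function(values, pixel_counts, method, fps) {
  structure(list(values = as.numeric(values),
                 pixel_counts = as.integer(pixel_counts),
                 method = method, fps = fps,
                 missing = which(pixel_counts == 0L),
                 time = (seq_along(values) - 1) / fps),
            class = "roi_series")
}

#' Extract a per-frame ROI temperature series
#'
#' Fuses a mask sequence with the co-registered thermal sequence: for every
#' frame, the in-mask temperatures are aggregated with [roi_aggregate()].
#' Frames with empty masks are recorded as missing (`NA` value, pixel count
#' 0) and listed in `missing`; downstream smoothing bridges short gaps.
#'
#' @param thermal A [thermal_sequence()].
#' @param masks A [mask_sequence()] aligned to `thermal` (same frame count
#'   and dimensions).
#' @param method Aggregation statistic: `"mean"`, `"max"` or `"sum"`.
#' @return An object of class `roi_series`: list with `values` (degC, or
#'   degC x pixels for `sum`), `pixel_counts`, `method`, `fps`, `missing`
#'   (frame indices with empty masks) and `time` (seconds).
#' @export
extract_series <- function(thermal, masks, method = c("mean", "max", "sum")) {
  stopifnot(inherits(thermal, "thermal_sequence"),
            inherits(masks, "mask_sequence"))
  method <- match.arg(method)
  check_aligned(thermal, masks, "thermal and mask sequences")
  n <- n_frames(thermal)
  values <- rep(NA_real_, n)
  counts <- integer(n)
  for (t in seq_len(n)) {
    v <- roi_values(thermal$frames[, , t], masks$frames[, , t])
    counts[t] <- length(v)
    if (counts[t]) values[t] <- roi_aggregate(v, method)
  }
  new_roi_series(values, counts, method, thermal$fps)
}

#' Total temperature-value count of a recording
#'
#' Bookkeeping helper: the number of temperature values in a recording of
#' `frames` frames of `height x width` pixels. The frame count may instead be
#' given as `fps * duration`; e.g. one minute of 640 x 480 at 10 fps holds
#' 184,320,000 values.
#'
#' @param height,width Frame dimensions in pixels.
#' @param frames Number of frames; omit to derive it from `fps * duration`.
#' @param fps Frame rate (frames/second), used with `duration`.
#' @param duration Recording length in seconds, used with `fps`.
#' @return Total value count (numeric, exact for integer inputs).
#' @examples
#' value_count(height = 640, width = 480, fps = 10, duration = 60)
#' @export
value_count <- function(height, width, frames = NULL, fps = NULL,
                        duration = NULL) {
  if (is.null(frames)) {
    if (is.null(fps) || is.null(duration))
      stop("give either `frames` or both `fps` and `duration`", call. = FALSE)
    if (fps <= 0 || duration <= 0)
      stop("fps and duration must be positive", call. = FALSE)
    frames <- fps * duration
  }
  if (frames <= 0 || height <= 0 || width <= 0)
    stop("all dimensions must be positive", call. = FALSE)
  as.numeric(frames) * as.numeric(height) * as.numeric(width)
}

#' @export
print.roi_series <- function(x, ...) {
  cat(sprintf("<roi_series> method '%s', %d frames at %g fps (%d missing)\n",
              x$method, length(x$values), x$fps, length(x$missing)))
  ok <- is.finite(x$values)
  if (any(ok))
    cat(sprintf("  value range: %.3f .. %.3f, pixel counts %d .. %d\n",
                min(x$values[ok]), max(x$values[ok]),
                min(x$pixel_counts[ok]), max(x$pixel_counts[ok])))
  invisible(x)
}
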