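#' Gaussian smoothing window
#'
#' Symmetric window of `window_len` weights proportional to
#' `exp(-k^2 / (2 * sigma^2))` for `k = -(m), ..., m`, normalized to sum to
#' one (unit DC gain, so constants pass through unchanged).
#'
#' @param window_len Odd window length in samples (>= 3).
#' @param sigma Width parameter in samples (> 0).
#' @return Numeric weight vector of length `window_len`.
#' @export
gaussian_kernel <- function(window_len, sigma) {
  if (window_len < 3 || window_len %% 2 == 0)
    stop("window_len must be odd and >= 3", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  k <- seq.int(-(window_len - 1) / 2, (window_len - 1) / 2)
  w <- exp(-k^2 / (2 * sigma^2))
  w / sum(w)
}

# Default window: 1 s of samples rounded up to odd, sigma = window/6. The
# window must stay shorter than the shortest breath period in the supported
# band (1 s at 60 breaths/min), otherwise the kernel's gain at the breathing
# frequency drops low enough to bury the peaks under boundary effects.
default_kernel_params <- function(fps) {
  len <- as.integer(ceiling(fps))
  if (len %% 2L == 0L) len <- len + 1L
  len <- max(len, 3L)
  list(window_len = len, sigma = len / 6)
}

# Bridge short empty-mask gaps by linear interpolation (gaps <= max_gap_s);
# longer gaps split the trace and the longest contiguous segment is kept.
prepare_trace_values <- function(values, fps, max_gap_s = 1) {
  x <- zoo::na.approx(values, na.rm = FALSE,
                      maxgap = max(1L, as.integer(round(max_gap_s * fps))))
  if (!anyNA(x)) return(list(values = x, start = 1L))
  ok <- !is.na(x)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  good <- which(r$values)
  if (!length(good)) stop("series contains no usable samples", call. = FALSE)
  pick <- good[which.max(r$lengths[good])]
  list(values = x[starts[pick]:ends[pick]], start = starts[pick])
}

#' Smooth a breathing series with a Gaussian window
#'
#' Suppresses frame-to-frame ripple in the ROI temperature series by
#' convolution with a normalized Gaussian window, using reflected-boundary
#' padding so the output has the same length as the (gap-handled) input.
#' Missing frames (empty masks) are bridged by linear interpolation when the
#' gap is at most `max_gap_s` seconds; a longer gap splits the trace and the
#' longest contiguous segment is smoothed (its frame offset is recorded in
#' `start_index`).
#'
#' @param series A [roi_series][extract_series()] object, or a plain numeric
#'   vector (then `fps` must be given).
#' @param window_len,sigma Kernel parameters (see [gaussian_kernel()]);
#'   defaults: a 1-second window rounded up to odd length, `sigma =
#'   window_len / 6`. The default window is kept shorter than the shortest
#'   breath period in the supported 10-60 breaths/min band so breathing
#'   peaks survive smoothing at every rate.
#' @param fps Frame rate, required when `series` is a bare vector.
#' @param max_gap_s Longest gap in seconds bridged by interpolation.
#' @return An object of class `breath_trace`: list with `values`, `fps`,
#'   `method`, `kernel_params` and `start_index` (1-based frame offset of the
#'   trace within the original series).
#' @export
smooth_series <- function(series, window_len = NULL, sigma = NULL, fps = NULL,
                          max_gap_s = 1) {
  if (inherits(series, "roi_series")) {
    values <- series$values; fps <- series$fps; method <- series$method
  } else {
    if (is.null(fps)) stop("`fps` required for a bare numeric series", call. = FALSE)
    values <- as.numeric(series); method <- NA_character_
  }
  p <- default_kernel_params(fps)
  if (is.null(window_len)) window_len <- p$window_len
  if (is.null(sigma)) sigma <- window_len / 6
  w <- gaussian_kernel(window_len, sigma)
  seg <- prepare_trace_values(values, fps, max_gap_s)
  x <- seg$values
  m <- (window_len - 1) / 2
  if (length(x) <= m)
    stop(sprintf("series too short to smooth: %d usable samples for a %d-sample window",
                 length(x), window_len), call. = FALSE)
  if (length(unique(x)) == 1L) {
    # constant input: unit DC gain holds exactly, bypass the convolution so
    # the constant is preserved to the bit, not just to rounding error
    sm_values <- x
  } else {
    padded <- c(x[(m + 1):2], x, x[(length(x) - 1):(length(x) - m)])
    sm <- stats::filter(padded, w, method = "convolution", sides = 2)
    sm_values <- as.numeric(sm[(m + 1):(m + length(x))])
  }
  structure(list(values = sm_values,
                 fps = fps, method = method,
                 kernel_params = list(window_len = window_len, sigma = sigma),
                 start_index = seg$start),
            class = "breath_trace")
}

#' Detect breath events as prominent peaks
#'
#' Strict local maxima of the trace (plateaus of equal values count once, at
#' their center) filtered by topographic prominence of at least
#' `min_prominence` times the trace range, then thinned so kept peaks are at
#' least `min_distance_s` seconds apart (higher peaks win). Peaks mark
#' exhalations (warm phase); deterministic.
#'
#' @param trace A [breath_trace][smooth_series()] object or numeric vector
#'   (then `fps` is required).
#' @param min_prominence Prominence threshold as a fraction of the trace
#'   range, in (0, 1); default 0.3.
#' @param min_distance_s Minimum separation between events in seconds.
#' @param fps Frame rate when `trace` is a bare vector.
#' @return Integer vector of event sample indices (within the trace),
#'   strictly increasing; empty for a flat trace.
#' @export
detect_peaks <- function(trace, min_prominence = 0.3, min_distance_s = 0.5,
                         fps = NULL) {
  if (inherits(trace, "breath_trace")) {
    x <- trace$values; fps <- trace$fps
  } else {
    if (is.null(fps)) stop("`fps` required for a bare numeric trace", call. = FALSE)
    x <- as.numeric(trace)
  }
  if (min_prominence <= 0 || min_prominence >= 1)
    stop("min_prominence must be in (0, 1)", call. = FALSE)
  if (min_distance_s <= 0) stop("min_distance_s must be > 0", call. = FALSE)
  rng <- diff(range(x))
  if (rng == 0 || length(x) < 3) return(integer())

  # candidate maxima with plateau handling: runs of equal values flanked by
  # strictly lower neighbours, peak placed at the plateau center
  r <- rle(x)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  cand <- integer()
  if (nr >= 3) {
    interior <- 2:(nr - 1)
    is_pk <- r$values[interior] > r$values[interior - 1] &
      r$values[interior] > r$values[interior + 1]
    pk <- interior[is_pk]
    cand <- starts[pk] + (r$lengths[pk] - 1L) %/% 2L
  }
  if (!length(cand)) return(integer())

  prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
  keep <- cand[prom >= min_prominence * rng]
  if (!length(keep)) return(integer())

  # min-distance thinning: process by descending height, ties by index
  ord <- keep[order(-x[keep], keep)]
  min_gap <- min_distance_s * fps
  kept <- integer()
  for (i in ord)
    if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  sort(kept)
}

# Topographic prominence of the local maximum at index i: height above the
# higher of the two key saddles (minima between the peak and the nearest
# strictly higher ground on each side, or the series end).
peak_prominence <- function(x, i) {
  h <- x[i]
  left <- if (i == 1L) h else {
    higher <- which(x[1:(i - 1L)] > h)
    lo <- if (length(higher)) max(higher) + 1L else 1L
    min(x[lo:(i - 1L)])
  }
  right <- if (i == length(x)) h else {
    higher <- which(x[(i + 1L):length(x)] > h)
    hi <- if (length(higher)) i + min(higher) - 1L else length(x)
    min(x[(i + 1L):hi])
  }
  h - max(left, right)
}

#' Respiration rate from the five-breath rule
#'
#' Converts the time taken to complete five breaths into breaths per minute:
#' `5 / duration_s * 60`. Ten seconds for five breaths gives 30 breaths/min.
#'
#' @param duration_s Time in seconds to complete five breaths (> 0).
#' @return Respiration rate in breaths per minute.
#' @examples
#' rr_from_five_breaths(10)  # 30
#' @export
rr_from_five_breaths <- function(duration_s) {
  if (!is.numeric(duration_s) || any(duration_s <= 0))
    stop("duration_s must be > 0", call. = FALSE)
  5 / duration_s * 60
}

#' Estimate respiration rate from a breath trace
#'
#' Detects breath events with [detect_peaks()] and converts them to breaths
#' per minute. The primary rule mirrors the observer protocol: the time from
#' the 1st to the 6th detected peak spans five complete breaths and is
#' converted with [rr_from_five_breaths()]. With fewer than 6 (but at least
#' 2) peaks, the fallback is the reciprocal mean inter-peak interval,
#' `60 / mean(diff(times))`.
#'
#' @param trace A [breath_trace][smooth_series()] object.
#' @param min_prominence,min_distance_s Passed to [detect_peaks()].
#' @param invert Detect troughs instead of peaks (for conventions where
#'   inhalation dominates the signal).
#' @return An object of class `rr_estimate`: list with `rate_bpm`,
#'   `n_events`, `window_duration` (seconds spanned by the events used),
#'   `event_indices` (frame indices in the original series) and `rule`
#'   (`"five_breaths"` or `"mean_interval"`).
#' @export
estimate_rr <- function(trace, min_prominence = 0.3, min_distance_s = 0.5,
                        invert = FALSE) {
  stopifnot(inherits(trace, "breath_trace"))
  work <- trace
  if (invert) work$values <- -work$values
  pk <- detect_peaks(work, min_prominence, min_distance_s)
  if (length(pk) < 2)
    stop("no breathing signal: fewer than 2 breath events detected",
         call. = FALSE)
  if (length(pk) >= 6) {
    dur <- (pk[6] - pk[1]) / trace$fps
    rate <- rr_from_five_breaths(dur)
    rule <- "five_breaths"
  } else {
    dur <- (pk[length(pk)] - pk[1]) / trace$fps
    rate <- 60 / (mean(diff(pk)) / trace$fps)
    rule <- "mean_interval"
  }
  structure(list(rate_bpm = rate, n_events = length(pk),
                 window_duration = dur,
                 event_indices = pk + trace$start_index - 1L,
                 rule = rule),
            class = "rr_estimate")
}

#' @export
print.rr_estimate <- function(x, ...) {
  cat(sprintf("<rr_estimate> %.2f breaths/min (%s rule, %d events over %.1f s)\n",
              x$rate_bpm, x$rule, x$n_events, x$window_duration))
  invisible(x)
}
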