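#' Ordinary least-squares agreement regression
#'
#' Agreement between two respiration-rate series (e.g. algorithm-derived
#' versus reference rates): OLS with intercept via [stats::lm()], reporting
#' the slope, intercept, coefficient of determination and the two-sided
#' p-value of the zero-slope test.
#'
#' @param x Reference (regressor) values, non-constant, length >= 3.
#' @param y Values regressed on `x`, same length.
#' @return An object of class `rr_regression`: list with `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`.
#' @export
rr_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate input: x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared,
                 p_value = s$coefficients[2, 4],
                 n = length(x)),
            class = "rr_regression")
}

#' @export
print.rr_regression <- function(x, ...) {
  cat(sprintf("<rr_regression> y = %.4f x + %.4f, R^2 = %.4f, p = %.3g, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Rate-recovery simulation experiment
#'
#' Synthetic analogue of an agreement study between reference and
#' algorithm-derived respiration rates: `n_recordings` scenes are generated
#' with true rates drawn uniformly from `rate_range`, the full pipeline is
#' run on each (exact ground-truth masks, mean aggregation, Gaussian
#' smoothing, peak-based rate estimation), and estimated rates are regressed
#' on true rates. Mask statistics are resolution-independent because the
#' masks are exact, so the default scene uses reduced 160 x 120 frames with
#' proportionally scaled nostril geometry.
#'
#' @param n_recordings Number of simulated recordings (>= 3).
#' @param rate_range Length-2 interval of true rates in breaths/min.
#' @param noise_sd Sensor noise sd in degC (default 0.07, the device
#'   sensitivity).
#' @param seed Integer seed controlling the sampled rates and scene noise.
#' @param amplitude Breathing half peak-to-trough amplitude, degC.
#' @param duration,fps Recording length (s) and frame rate.
#' @param frame_height,frame_width Simulated frame size in pixels; nostril
#'   geometry is scaled by `frame_height / 640`.
#' @return List with `table` (data frame: `recording`, `true_bpm`,
#'   `estimated_bpm`, `n_events`, `rule`), `regression` (an
#'   [rr_regression()] on the successful recordings) and `n_failed`.
#' @export
recovery_experiment <- function(n_recordings = 50, rate_range = c(10, 60),
                                noise_sd = 0.07, seed = 1L, amplitude = 2,
                                duration = 60, fps = 10,
                                frame_height = 160, frame_width = 120) {
  if (n_recordings < 3) stop("need n_recordings >= 3", call. = FALSE)
  draws <- with_local_seed(seed, list(
    rates = stats::runif(n_recordings, rate_range[1], rate_range[2]),
    scene_seeds = sample.int(.Machine$integer.max, n_recordings)))
  scale <- frame_height / 640
  est <- rep(NA_real_, n_recordings)
  nev <- rep(NA_integer_, n_recordings)
  rule <- rep(NA_character_, n_recordings)
  for (i in seq_len(n_recordings)) {
    cfg <- scene_config(frame_height = frame_height, frame_width = frame_width,
                        fps = fps, duration = duration,
                        rate_bpm = draws$rates[i], amplitude = amplitude,
                        noise_sd = noise_sd,
                        motion_amplitude = 5 * scale,
                        nostril_radii = c(20, 14) * scale,
                        nostril_separation = 90 * scale,
                        seed = draws$scene_seeds[i])
    scene <- generate_scene(cfg, rgb = FALSE, annotation_masks = FALSE)
    series <- extract_series(scene$thermal, scene$gt_masks, "mean")
    r <- tryCatch(estimate_rr(smooth_series(series)), error = function(e) NULL)
    if (!is.null(r)) {
      est[i] <- r$rate_bpm; nev[i] <- r$n_events; rule[i] <- r$rule
    }
    rm(scene, series)
  }
  n_failed <- sum(is.na(est))
  if (n_failed)
    message(n_failed, " recording(s) failed rate estimation and were excluded")
  tab <- data.frame(recording = seq_len(n_recordings),
                    true_bpm = draws$rates, estimated_bpm = est,
                    n_events = nev, rule = rule)
  list(table = tab,
       regression = rr_regression(tab$true_bpm, tab$estimated_bpm),
       n_failed = n_failed)
}

# Change-points of the mask pixel-count series: frames t such that the count
# changes by more than 10% between t and t+1 (empty frames are skipped).
pixel_count_changepoints <- function(counts, rel_tol = 0.1) {
  n <- length(counts)
  if (n < 2) return(integer())
  a <- counts[-n]; b <- counts[-1]
  ok <- a > 0 & b > 0
  which(ok & abs(b / a - 1) > rel_tol)
}

#' Compare the three aggregation methods on one scene
#'
#' Reproduces the qualitative method-comparison on a synthetic scene: the
#' max, mean and sum series are extracted with the ground-truth masks, and
#' each is screened for the two known artifacts. A *level shift* is flagged
#' when, around a change-point of the mask pixel-count series, the ratio of
#' the trailing to the leading `window_s`-second trace medians exceeds
#' `shift_threshold` (in either direction) — the signature of sum-method
#' corruption by camera-distance or nostril-count changes. A *low amplitude*
#' flag marks traces whose breathing oscillation (largest peak-to-trough
#' range of the smoothed trace within any constant-pixel-count segment,
#' normalized to degC for the sum method) falls below `min_amplitude`.
#'
#' @param scene A [generate_scene()] bundle.
#' @param window_s Median window around change-points, seconds.
#' @param shift_threshold Ratio above which a level shift is flagged
#'   (default 1.25).
#' @param min_amplitude Detectability threshold in degC for the oscillation
#'   amplitude (default 0.2).
#' @return An object of class `method_comparison`: list with `series` (the
#'   three `roi_series`), `flags` (data frame: `method`, `level_shift`,
#'   `low_amplitude`, `max_shift_ratio`), `shift_ratios` (per change-point,
#'   per method), `estimates` (per-method `rr_estimate` or `NULL`), and
#'   `change_points`.
#' @export
method_comparison <- function(scene, window_s = 5, shift_threshold = 1.25,
                              min_amplitude = 0.2) {
  stopifnot(inherits(scene, "scene_bundle"))
  methods <- c("max", "mean", "sum")
  series <- lapply(methods, function(m)
    extract_series(scene$thermal, scene$gt_masks, m))
  names(series) <- methods
  counts <- series$mean$pixel_counts
  cps <- pixel_count_changepoints(counts)
  w <- max(1L, as.integer(round(window_s * scene$config$fps)))
  n <- length(counts)

  shift_ratio <- function(values, cp) {
    lead <- values[max(1L, cp - w + 1L):cp]
    trail <- values[(cp + 1L):min(n, cp + w)]
    stats::median(trail, na.rm = TRUE) / stats::median(lead, na.rm = TRUE)
  }
  ratios <- lapply(series, function(s)
    vapply(cps, function(cp) shift_ratio(s$values, cp), numeric(1)))

  # oscillation amplitude within constant-count segments, on the degC scale
  seg_id <- cumsum(c(1L, as.integer(seq_len(n - 1L) %in% cps)))
  osc_amplitude <- function(s) {
    tr <- tryCatch(smooth_series(s), error = function(e) NULL)
    if (is.null(tr)) return(NA_real_)
    v <- tr$values
    ids <- seg_id[tr$start_index + seq_along(v) - 1L]
    rngs <- vapply(split(seq_along(v), ids), function(ix) {
      if (length(ix) < 3) return(0)
      scale <- if (s$method == "sum")
        stats::median(s$pixel_counts[tr$start_index + ix - 1L]) else 1
      diff(range(v[ix])) / scale
    }, numeric(1))
    max(rngs)
  }
  amps <- vapply(series, osc_amplitude, numeric(1))

  flags <- data.frame(
    method = methods,
    level_shift = vapply(methods, function(m) {
      r <- ratios[[m]]
      length(r) > 0 && any(pmax(r, 1 / r) > shift_threshold)
    }, logical(1)),
    low_amplitude = !is.na(amps) & amps < min_amplitude,
    max_shift_ratio = vapply(methods, function(m) {
      r <- ratios[[m]]
      if (!length(r)) NA_real_ else r[which.max(pmax(r, 1 / r))]
    }, numeric(1)),
    row.names = NULL)

  estimates <- lapply(series, function(s)
    tryCatch(estimate_rr(smooth_series(s)), error = function(e) NULL))

  structure(list(series = series, flags = flags, shift_ratios = ratios,
                 estimates = estimates, change_points = cps),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> %d pixel-count change-point(s)\n",
              length(x$change_points)))
  for (i in seq_len(nrow(x$flags))) {
    f <- x$flags[i, ]
    est <- x$estimates[[f$method]]
    cat(sprintf("  %-4s: level shift %-5s (max ratio %s), low amplitude %-5s, RR %s\n",
                f$method, f$level_shift,
                ifelse(is.na(f$max_shift_ratio), "-",
                       sprintf("%.2f", f$max_shift_ratio)),
                f$low_amplitude,
                if (is.null(est)) "n/a" else sprintf("%.1f bpm", est$rate_bpm)))
  }
  invisible(x)
}
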