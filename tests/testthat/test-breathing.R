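# Hand-built breath trace for rate-rule tests.
make_trace <- function(values, fps) {
  structure(list(values = values, fps = fps, method = "mean",
                 kernel_params = list(window_len = NA, sigma = NA),
                 start_index = 1L),
            class = "breath_trace")
}

test_that("the Gaussian window is normalized, symmetric, and correctly shaped", {
  for (p in list(c(5, 1), c(9, 2.5), c(21, 3.5))) {
    w <- gaussian_kernel(p[1], p[2])
    expect_equal(sum(w), 1)
    expect_equal(w, rev(w))
    expect_true(all(w > 0))
  }
  w <- gaussian_kernel(5, 1)
  expect_equal(w[3] / w[1], exp(0) / exp(-2))
  expect_error(gaussian_kernel(4, 1), "odd")
  expect_error(gaussian_kernel(1, 1), "odd")
  expect_error(gaussian_kernel(5, 0), "sigma")
})

test_that("smoothing preserves constants exactly and has unit DC gain", {
  s <- irtbreath:::new_roi_series(rep(33.2, 50), rep(100L, 50), "mean", 10)
  tr <- smooth_series(s)
  expect_equal(tr$values, rep(33.2, 50))
  expect_identical(length(tr$values), 50L)
})

test_that("an interior unit impulse smooths to the kernel itself", {
  x <- numeric(41); x[21] <- 1
  tr <- smooth_series(x, window_len = 9, sigma = 1.5, fps = 10)
  expect_equal(tr$values[17:25], gaussian_kernel(9, 1.5))
  expect_equal(tr$values[c(1:10, 32:41)], numeric(20))
})

test_that("smoothing never increases sample variance", {
  set.seed(17)
  for (i in 1:10) {
    x <- stats::rnorm(120, 33, runif(1, 0.1, 3)) +
      sin(2 * pi * 0.5 * (0:119) / 10) * runif(1, 0, 2)
    tr <- smooth_series(x, fps = 10)
    expect_lte(stats::var(tr$values), stats::var(x))
  }
})

test_that("a 30 bpm sinusoid is attenuated by the kernel gain with peaks in place", {
  fps <- 10; f <- 0.5  # 30 bpm
  t <- (0:599) / fps
  x <- 33 + 2 * sin(2 * pi * f * t)
  w <- gaussian_kernel(21, 3.5)
  k <- seq(-10, 10)
  gain <- abs(sum(w * exp(-1i * 2 * pi * f / fps * k)))
  tr <- smooth_series(x, window_len = 21, sigma = 3.5, fps = fps)
  interior <- 30:570
  expect_equal(max(tr$values[interior]) - 33, 2 * gain, tolerance = 1e-3)
  raw_peaks <- detect_peaks(x, fps = fps)
  sm_peaks <- detect_peaks(tr$values, fps = fps)
  common <- raw_peaks[raw_peaks > 30 & raw_peaks < 570]
  expect_true(all(common %in% sm_peaks))
})

test_that("gap handling interpolates short gaps and keeps the longest segment", {
  v <- sin(2 * pi * 0.5 * (0:99) / 10) + 33
  v[40:45] <- NA  # 0.6 s gap: interpolated
  s <- irtbreath:::new_roi_series(v, ifelse(is.na(v), 0L, 50L), "mean", 10)
  tr <- smooth_series(s)
  expect_identical(length(tr$values), 100L)
  expect_identical(tr$start_index, 1L)
  v2 <- v
  v2[30:55] <- NA  # 2.6 s gap: split, longest segment kept
  s2 <- irtbreath:::new_roi_series(v2, ifelse(is.na(v2), 0L, 50L), "mean", 10)
  tr2 <- smooth_series(s2)
  expect_identical(tr2$start_index, 56L)
  expect_identical(length(tr2$values), 45L)
})

test_that("peak detection finds every period of a clean sinusoid", {
  fps <- 10
  t <- (0:199) / fps  # 20 s at 30 bpm: 10 full periods
  x <- sin(2 * pi * 0.5 * t)
  pk <- detect_peaks(x, fps = fps)
  expect_identical(length(pk), 10L)
  expect_equal(pk, seq(6, 186, by = 20))
  expect_identical(detect_peaks(rep(3, 100), fps = fps), integer())
})

test_that("peak detection is robust to small noise at default prominence", {
  fps <- 10
  t <- (0:199) / fps
  clean <- sin(2 * pi * 0.5 * t)
  set.seed(23)
  noisy <- clean + stats::rnorm(length(t), sd = 0.05)
  sm <- smooth_series(noisy, window_len = 9, sigma = 1.5, fps = fps)
  pk_clean <- detect_peaks(clean, fps = fps)
  pk_noisy <- detect_peaks(sm$values, fps = fps)
  expect_identical(length(pk_noisy), length(pk_clean))
  expect_true(all(abs(pk_noisy - pk_clean) <= 2))
})

test_that("plateau maxima count once, at their center", {
  x <- c(0, 1, 2, 2, 2, 1, 0, 3, 0)
  pk <- detect_peaks(x, min_prominence = 0.2, min_distance_s = 0.1, fps = 10)
  expect_identical(pk, c(4L, 8L))
})

test_that("five-breath conversion matches the worked example", {
  expect_identical(rr_from_five_breaths(10), 30)
  expect_identical(rr_from_five_breaths(60), 5)
  expect_identical(rr_from_five_breaths(20), 15)
  expect_error(rr_from_five_breaths(0), "duration")
  expect_error(rr_from_five_breaths(-3), "duration")
})

test_that("rate estimation uses the five-breath window with >= 6 peaks", {
  # 6+ peaks exactly 2 s apart -> five breaths in 10 s -> 30 bpm
  t <- (0:149) / 10
  tr <- make_trace(sin(2 * pi * t / 2), fps = 10)
  est <- estimate_rr(tr)
  expect_equal(est$rate_bpm, 30)
  expect_identical(est$rule, "five_breaths")
  expect_equal(est$window_duration, 10)
  expect_true(all(diff(est$event_indices) > 0))
})

test_that("rate estimation falls back to mean inter-peak interval", {
  # 3 peaks spaced exactly 3 s apart -> 60/3 = 20 bpm
  i <- 1:80
  x <- exp(-(i - 10)^2 / 8) + exp(-(i - 40)^2 / 8) + exp(-(i - 70)^2 / 8)
  est <- estimate_rr(make_trace(x, fps = 10))
  expect_identical(est$n_events, 3L)
  expect_identical(est$rule, "mean_interval")
  expect_equal(est$rate_bpm, 20)
  expect_error(estimate_rr(make_trace(rep(1, 50), fps = 10)), "no breathing")
})

test_that("polarity inversion recovers rates from trough-dominant signals", {
  t <- (0:299) / 10
  tr <- make_trace(33 - 2 * sin(2 * pi * t / 2), fps = 10)
  est <- estimate_rr(tr, invert = TRUE)
  expect_equal(est$rate_bpm, 30)
})

test_that("the full pipeline recovers a 20 bpm scene within 0.5 bpm", {
  cfg <- small_scene_config(duration = 60, rate_bpm = 20)
  scene <- generate_scene(cfg, rgb = FALSE, annotation_masks = FALSE)
  series <- extract_series(scene$thermal, scene$gt_masks, "mean")
  est <- estimate_rr(smooth_series(series))
  expect_lt(abs(est$rate_bpm - 20), 0.5)
})

test_that("estimates double when the true rate doubles", {
  rates <- c(15, 30)
  est <- vapply(rates, function(r) {
    cfg <- small_scene_config(duration = 60, rate_bpm = r)
    scene <- generate_scene(cfg, rgb = FALSE, annotation_masks = FALSE)
    estimate_rr(smooth_series(extract_series(scene$thermal, scene$gt_masks,
                                             "mean")))$rate_bpm
  }, numeric(1))
  expect_equal(est[2] / est[1], 2, tolerance = 0.05)
})
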