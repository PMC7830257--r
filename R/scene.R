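#' Synthetic scene configuration
#'
#' Parameters of the synthetic paired RGB/thermal recording used to validate
#' the pipeline at desk scale. The scene is a uniform ambient background with
#' one or two elliptical nostril openings whose interior temperature
#' oscillates with breathing (warm exhale, cool inhale), plus the acquisition
#' confounds seen in the field: slow translation of the nose in the frame,
#' camera-distance changes that rescale the apparent nostril size, alternating
#' one-vs-two nostril visibility, and additive per-pixel Gaussian sensor
#' noise at the camera's stated sensitivity.
#'
#' Defaults mirror the acquisition stream the pipeline targets: 640 x 480
#' frames at 10 fps for 60 s, nostril baseline 33 degC oscillating by
#' +/- 2 degC over a 25 degC background, sensor noise sd 0.07 degC.
#'
#' @param frame_height,frame_width Frame size in pixels.
#' @param fps Frames per second (> 0).
#' @param duration Recording length in seconds (> 0).
#' @param rate_bpm True respiration rate in breaths per minute (> 0).
#' @param baseline_temp Nostril interior temperature at mid-breath, degC.
#' @param amplitude Half peak-to-trough breathing oscillation, degC (>= 0).
#' @param ambient_temp Background temperature, degC.
#' @param noise_sd Additive i.i.d. Gaussian sensor noise sd, degC (>= 0).
#' @param nostril_schedule Per-frame count of visible nostrils, each 1 or 2
#'   (a scalar is recycled to all frames).
#' @param distance_schedule Per-frame scale factor (> 0) applied to apparent
#'   nostril radii and separation (a scalar is recycled); emulates
#'   camera-to-animal distance changes.
#' @param motion_amplitude Amplitude in pixels of the slow sinusoidal
#'   translation of the nose center (0 disables motion).
#' @param nostril_radii Length-2 semi-axes in pixels of each elliptical
#'   nostril at scale 1: `c(column semi-axis, row semi-axis)`.
#' @param nostril_separation Center-to-center column distance in pixels
#'   between the two nostrils at scale 1.
#' @param seed Integer seed; the only stochastic element is the sensor noise,
#'   so identical seeds give bit-identical scenes.
#' @return A validated object of class `scene_config`.
#' @seealso [generate_scene()], [thermal_signal()]
#' @export
scene_config <- function(frame_height = 640, frame_width = 480, fps = 10,
                         duration = 60, rate_bpm = 30, baseline_temp = 33,
                         amplitude = 2, ambient_temp = 25, noise_sd = 0.07,
                         nostril_schedule = 2, distance_schedule = 1,
                         motion_amplitude = 5, nostril_radii = c(20, 14),
                         nostril_separation = 90, seed = 1L) {
  if (fps <= 0 || duration <= 0) stop("fps and duration must be > 0", call. = FALSE)
  if (rate_bpm <= 0) stop("rate_bpm must be > 0", call. = FALSE)
  if (amplitude < 0 || noise_sd < 0)
    stop("amplitude and noise_sd must be >= 0", call. = FALSE)
  if (length(nostril_radii) != 2L || any(nostril_radii <= 0))
    stop("nostril_radii must be two positive semi-axes", call. = FALSE)
  n <- as.integer(round(fps * duration))
  if (n < 1L) stop("duration too short for a single frame", call. = FALSE)
  nostril_schedule <- rep_len(as.integer(nostril_schedule), n)
  distance_schedule <- rep_len(as.numeric(distance_schedule), n)
  if (!all(nostril_schedule %in% c(1L, 2L)))
    stop("nostril_schedule entries must be 1 or 2", call. = FALSE)
  if (any(distance_schedule <= 0))
    stop("distance_schedule entries must be > 0", call. = FALSE)
  structure(
    list(frame_height = as.integer(frame_height),
         frame_width = as.integer(frame_width),
         fps = fps, duration = duration, rate_bpm = rate_bpm,
         baseline_temp = baseline_temp, amplitude = amplitude,
         ambient_temp = ambient_temp, noise_sd = noise_sd,
         nostril_schedule = nostril_schedule,
         distance_schedule = distance_schedule,
         motion_amplitude = motion_amplitude,
         nostril_radii = as.numeric(nostril_radii),
         nostril_separation = as.numeric(nostril_separation),
         seed = as.integer(seed), n_frames = n),
    class = "scene_config")
}

#' Breathing-driven nostril temperature
#'
#' Sinusoidal model of the temperature inside the nostril opening over the
#' breathing cycle: `baseline + amplitude * sin(2 * pi * rate_bpm / 60 * t)`.
#' The warm peak corresponds to exhalation, the cool trough to inhalation;
#' the period is `60 / rate_bpm` seconds.
#'
#' @param t Time in seconds (vectorized).
#' @param rate_bpm Respiration rate in breaths per minute (> 0).
#' @param baseline Mid-breath temperature, degC.
#' @param amplitude Half peak-to-trough oscillation, degC.
#' @return Nostril interior temperature(s) in degC.
#' @examples
#' thermal_signal(0.5, rate_bpm = 30, baseline = 33, amplitude = 2)  # 35
#' @export
thermal_signal <- function(t, rate_bpm, baseline, amplitude) {
  if (!is.numeric(rate_bpm) || rate_bpm <= 0)
    stop("rate_bpm must be > 0", call. = FALSE)
  baseline + amplitude * sin(2 * pi * (rate_bpm / 60) * t)
}

# Nostril geometry for one frame: centers (row, col) and scaled semi-axes.
# Motion is a slow two-axis sinusoid (periods 23 s and 17 s, well below the
# breathing band) so masks move smoothly without aliasing the breath signal.
scene_geometry <- function(config, t_index) {
  t <- (t_index - 1) / config$fps
  s <- config$distance_schedule[t_index]
  cr <- (config$frame_height + 1) / 2 +
    config$motion_amplitude * sin(2 * pi * t / 23)
  cc <- (config$frame_width + 1) / 2 +
    config$motion_amplitude * sin(2 * pi * t / 17)
  half_sep <- s * config$nostril_separation / 2
  k <- config$nostril_schedule[t_index]
  centers <- if (k == 2L) {
    rbind(c(cr, cc - half_sep), c(cr, cc + half_sep))
  } else {
    rbind(c(cr, cc - half_sep))  # single visible nostril: the left one
  }
  list(centers = centers,
       rx = s * config$nostril_radii[1],  # column semi-axis
       ry = s * config$nostril_radii[2])  # row semi-axis
}

# Linear indices of one ellipse's interior, computed on its bounding box only.
ellipse_indices <- function(center, rx, ry, H, W) {
  rows <- max(1L, floor(center[1] - ry)):min(H, ceiling(center[1] + ry))
  cols <- max(1L, floor(center[2] - rx)):min(W, ceiling(center[2] + rx))
  d2 <- outer(((rows - center[1]) / ry)^2, ((cols - center[2]) / rx)^2, "+")
  sel <- which(d2 <= 1)
  if (!length(sel)) return(integer())
  ri <- ((sel - 1L) %% length(rows)) + 1L
  ci <- ((sel - 1L) %/% length(rows)) + 1L
  (cols[ci] - 1L) * H + rows[ri]
}

#' Generate a synthetic paired recording with ground truth
#'
#' Renders thermal frames (ambient background, nostril interiors carrying
#' [thermal_signal()] at the frame time, plus optional i.i.d. Gaussian noise
#' over the whole frame), exact ground-truth nostril masks, per-nostril
#' ground-truth annotations, and optionally a cosmetic RGB rendering (flat
#' background with a darker nose region). The seed controls only the noise:
#' two configs differing only in seed share identical ground-truth masks.
#'
#' @param config A [scene_config()].
#' @param rgb Render the RGB frames? The RGB content is cosmetic (a darker
#'   nose region on a flat background) and can be skipped to save memory in
#'   large simulation batches.
#' @param annotation_masks Attach per-object instance masks to the
#'   ground-truth annotations? Boxes are always present; full-frame instance
#'   masks are only needed for mask-IoU scoring and can be skipped in large
#'   simulation batches.
#' @return An object of class `scene_bundle` with elements `rgb` (an
#'   [rgb_sequence()] or `NULL`), `thermal`, `gt_masks`, `gt_annotations`,
#'   `true_rate_bpm` and `config`.
#' @examples
#' sc <- scene_config(frame_height = 60, frame_width = 80, duration = 2,
#'                    nostril_radii = c(8, 6), nostril_separation = 30,
#'                    motion_amplitude = 2)
#' scene <- generate_scene(sc)
#' scene$thermal
#' @export
generate_scene <- function(config, rgb = TRUE, annotation_masks = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  H <- config$frame_height; W <- config$frame_width; n <- config$n_frames
  times <- (seq_len(n) - 1) / config$fps

  # Geometry first (deterministic, seed-independent).
  masks <- array(0L, dim = c(H, W, n))
  ann_rows <- list(); ann_masks <- list(); a <- 0L
  idx_per_frame <- vector("list", n)
  for (t in seq_len(n)) {
    g <- scene_geometry(config, t)
    # bounds check: ellipse bounding boxes must stay inside the frame
    for (j in seq_len(nrow(g$centers))) {
      ctr <- g$centers[j, ]
      if (ctr[1] - g$ry < 0.5 || ctr[1] + g$ry > H + 0.5 ||
          ctr[2] - g$rx < 0.5 || ctr[2] + g$rx > W + 0.5)
        stop(sprintf("nostril ellipse leaves the frame at frame %d", t),
             call. = FALSE)
    }
    frame_idx <- integer()
    for (j in seq_len(nrow(g$centers))) {
      idx <- ellipse_indices(g$centers[j, ], g$rx, g$ry, H, W)
      frame_idx <- c(frame_idx, idx)
      a <- a + 1L
      rr <- range(((idx - 1L) %% H) + 1L)
      cc <- range(((idx - 1L) %/% H) + 1L)
      ann_rows[[a]] <- data.frame(frame = t, r0 = rr[1] - 1L, c0 = cc[1] - 1L,
                                  r1 = rr[2], c1 = cc[2])
      if (isTRUE(annotation_masks)) {
        m <- matrix(0L, H, W); m[idx] <- 1L
        ann_masks[[a]] <- m
      }
    }
    masks[(t - 1L) * H * W + frame_idx] <- 1L
    idx_per_frame[[t]] <- frame_idx
  }

  # Thermal rendering; noise is the only use of the RNG.
  thermal <- array(config$ambient_temp, dim = c(H, W, n))
  sig <- thermal_signal(times, config$rate_bpm, config$baseline_temp,
                        config$amplitude)
  for (t in seq_len(n))
    thermal[(t - 1L) * H * W + idx_per_frame[[t]]] <- sig[t]
  if (config$noise_sd > 0) {
    thermal <- thermal + with_local_seed(config$seed,
      array(stats::rnorm(length(thermal), sd = config$noise_sd), dim(thermal)))
  }

  rgb_seq <- NULL
  if (isTRUE(rgb)) {
    rgb_frames <- array(180, dim = c(H, W, 3L, n))  # flat light background
    for (t in seq_len(n)) {
      g <- scene_geometry(config, t)
      nose_ctr <- colMeans(g$centers)
      nose <- ellipse_indices(nose_ctr,
                              rx = g$rx + config$nostril_separation *
                                config$distance_schedule[t] / 2,
                              ry = g$ry * 1.8, H, W)
      off <- (t - 1L) * 3L * H * W
      for (ch in 0:2) {
        rgb_frames[off + ch * H * W + nose] <- 90   # darker nose region
        rgb_frames[off + ch * H * W + idx_per_frame[[t]]] <- 40  # nostrils
      }
    }
    rgb_seq <- rgb_sequence(rgb_frames)
  }

  ann <- annotation_set(do.call(rbind, ann_rows),
                        masks = if (isTRUE(annotation_masks)) ann_masks)
  structure(
    list(rgb = rgb_seq,
         thermal = thermal_sequence(thermal, fps = config$fps),
         gt_masks = mask_sequence(masks),
         gt_annotations = ann,
         true_rate_bpm = config$rate_bpm,
         config = config),
    class = "scene_bundle")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so scene generation never perturbs user code.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.scene_bundle <- function(x, ...) {
  cat(sprintf("<scene_bundle> %d frames %dx%d at %g fps, true rate %g bpm%s\n",
              x$config$n_frames, x$config$frame_height, x$config$frame_width,
              x$config$fps, x$true_rate_bpm,
              if (is.null(x$rgb)) " (thermal only)" else ""))
  invisible(x)
}
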