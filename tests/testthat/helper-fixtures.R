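# Shared fixtures and independent oracles used across the suite.

# Small scene with geometry scaled from the default 640x480 stream, so mask
# statistics stay comparable while tests run at desk scale.
small_scene_config <- function(frame_height = 120, frame_width = 160,
                               duration = 10, fps = 10, rate_bpm = 30,
                               noise_sd = 0, motion_amplitude = 2,
                               nostril_radii = c(8, 6),
                               nostril_separation = 40, ...) {
  scene_config(frame_height = frame_height, frame_width = frame_width,
               duration = duration, fps = fps, rate_bpm = rate_bpm,
               noise_sd = noise_sd, motion_amplitude = motion_amplitude,
               nostril_radii = nostril_radii,
               nostril_separation = nostril_separation, ...)
}

# Independent box IoU oracle: enumerate the integer pixel cells of each
# half-open box on a grid and count intersection/union directly.
pixel_iou_oracle <- function(a, b) {
  cells <- function(bx) {
    g <- expand.grid(r = seq(bx[1], bx[3] - 1), c = seq(bx[2], bx[4] - 1))
    paste(g$r, g$c)
  }
  ca <- cells(a); cb <- cells(b)
  length(intersect(ca, cb)) / length(union(ca, cb))
}

# Independent AP oracle: greedy matching re-derived with pixel-grid IoU, then
# the precision envelope integrated by a fine Riemann sum over recall.
brute_ap_oracle <- function(dets, gts, iou_threshold = 0.5, grid = 2e5) {
  ord <- order(-dets$score, dets$frame, dets$r0, dets$c0, dets$r1, dets$c1,
               seq_len(nrow(dets)))
  taken <- rep(FALSE, nrow(gts))
  tp <- logical(length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    cand <- which(gts$frame == dets$frame[i] & !taken)
    if (!length(cand)) next
    ious <- vapply(cand, function(j)
      pixel_iou_oracle(unlist(dets[i, c("r0", "c0", "r1", "c1")]),
                       unlist(gts[j, c("r0", "c0", "r1", "c1")])),
      numeric(1))
    if (max(ious) > iou_threshold) {
      tp[k] <- TRUE
      taken[cand[which.max(ious)]] <- TRUE
    }
  }
  rec <- cumsum(tp) / nrow(gts)
  prec <- cumsum(tp) / seq_along(tp)
  r_grid <- seq(1 / grid, 1, by = 1 / grid)
  p_at <- vapply(r_grid, function(r) {
    ok <- which(rec >= r)
    if (!length(ok)) 0 else max(prec[ok])
  }, numeric(1))
  mean(p_at)
}

# Independent Otsu oracle: exhaustive scan of interior histogram edges with
# class weights/means accumulated by explicit loops over the bins.
brute_otsu_oracle <- function(values, n_bins = 256) {
  edges <- seq(min(values), max(values), length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  best <- -Inf; best_edge <- NA_real_
  for (e in 2:n_bins) {
    n0 <- 0; s0 <- 0; n1 <- 0; s1 <- 0
    for (b in seq_len(n_bins)) {
      if (b < e) { n0 <- n0 + counts[b]; s0 <- s0 + counts[b] * mids[b] }
      else { n1 <- n1 + counts[b]; s1 <- s1 + counts[b] * mids[b] }
    }
    if (n0 == 0 || n1 == 0) next
    bcv <- (n0 / (n0 + n1)) * (n1 / (n0 + n1)) * (s0 / n0 - s1 / n1)^2
    if (bcv > best) { best <- bcv; best_edge <- edges[e] }
  }
  best_edge
}

# Random small scored-detection fixture over a handful of frames.
random_detection_fixture <- function(seed, n_det, n_gt) {
  set.seed(seed)
  mk_box <- function(n) {
    r0 <- sample(0:20, n, TRUE); c0 <- sample(0:20, n, TRUE)
    data.frame(r0 = r0, c0 = c0,
               r1 = r0 + sample(3:12, n, TRUE),
               c1 = c0 + sample(3:12, n, TRUE))
  }
  gts <- cbind(data.frame(frame = sample(1:2, n_gt, TRUE)), mk_box(n_gt))
  base <- gts[sample(n_gt, n_det, TRUE), ]
  jit <- sample(0:6, n_det, TRUE)
  dets <- data.frame(frame = base$frame,
                     r0 = base$r0 + jit, c0 = base$c0 + jit,
                     r1 = base$r1 + jit, c1 = base$c1 + jit,
                     score = round(stats::runif(n_det), 2))
  list(dets = detections(dets), gts = annotation_set(gts))
}
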