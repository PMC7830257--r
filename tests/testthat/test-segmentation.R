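test_that("box IoU matches pixel enumeration and is symmetric", {
  a <- c(0, 0, 10, 10); b <- c(5, 5, 15, 15)
  expect_equal(iou_box(a, a), 1.0)
  expect_equal(iou_box(a, c(20, 20, 25, 25)), 0.0)
  expect_equal(iou_box(a, b), 25 / 175)
  expect_equal(iou_box(a, b), iou_box(b, a))
  set.seed(21)
  for (i in 1:10) {
    r0 <- sample(0:10, 2); c0 <- sample(0:10, 2)
    x <- c(r0[1], c0[1], r0[1] + sample(2:8, 1), c0[1] + sample(2:8, 1))
    y <- c(r0[2], c0[2], r0[2] + sample(2:8, 1), c0[2] + sample(2:8, 1))
    expect_equal(iou_box(x, y), pixel_iou_oracle(x, y))
  }
  expect_error(iou_box(c(0, 0, 0, 5), a), "degenerate")
})

test_that("mask IoU counts overlap pixels", {
  a <- matrix(0L, 6, 6); a[1:3, 1:3] <- 1L
  b <- matrix(0L, 6, 6); b[2:4, 2:4] <- 1L
  expect_equal(iou_mask(a, b), 4 / 14)
  expect_error(iou_mask(a * 0L, b * 0L), "degenerate")
})

test_that("matching is greedy, one-to-one, and strict at the threshold", {
  gt <- annotation_set(data.frame(frame = 1L, r0 = 0, c0 = 0, r1 = 10, c1 = 10))
  exact <- detections(data.frame(frame = 1L, r0 = 0, c0 = 0, r1 = 10, c1 = 10,
                                 score = 0.9))
  m <- match_detections(exact, gt)
  expect_identical(sum(m$tp), 1L)
  # two detections on the same ground truth: one TP, one FP
  two <- detections(data.frame(frame = c(1L, 1L), r0 = 0, c0 = 0, r1 = 10,
                               c1 = 10, score = c(0.9, 0.8)))
  m2 <- match_detections(two, gt)
  expect_identical(sum(m2$tp), 1L)
  expect_true(m2$tp[1] && !m2$tp[2])
  # IoU exactly at the threshold fails ("exceeds", strict)
  half <- detections(data.frame(frame = 1L, r0 = 0, c0 = 0, r1 = 10, c1 = 10,
                                score = 1))
  gt_half <- annotation_set(data.frame(frame = 1L, r0 = 0, c0 = 0,
                                       r1 = 5, c1 = 10))
  expect_identical(sum(match_detections(half, gt_half)$tp), 0L)
  expect_identical(nrow(match_detections(detections(two[0, ]), gt)), 0L)
})

test_that("the 5-ground-truth / 3-detection / 2-correct case gives 2/3 and 2/5", {
  # five objects in one image; three detections, two accurate
  gt <- annotation_set(data.frame(
    frame = 1L, r0 = c(0, 0, 20, 20, 40), c0 = c(0, 20, 0, 20, 40),
    r1 = c(10, 10, 30, 30, 50), c1 = c(10, 30, 10, 30, 50)))
  dets <- detections(data.frame(
    frame = 1L,
    r0 = c(0, 1, 100), c0 = c(0, 21, 100),
    r1 = c(10, 11, 110), c1 = c(10, 31, 110),
    score = c(0.95, 0.9, 0.85)))
  m <- match_detections(dets, gt, 0.5)
  expect_identical(sum(m$tp), 2L)
  pr <- precision_recall(sum(m$tp), nrow(dets), nrow(gt))
  expect_equal(unname(pr["precision"]), 2 / 3)
  expect_equal(unname(pr["recall"]), 2 / 5)
})

test_that("precision and recall follow their conventions", {
  expect_equal(precision_recall(4, 4, 4), c(precision = 1, recall = 1))
  expect_equal(precision_recall(0, 0, 5), c(precision = 0, recall = 0))
  expect_error(precision_recall(0, 3, 0), "undefined")
  expect_error(precision_recall(3, 2, 5), "exceed")
})

test_that("average precision matches the brute-force PR-integral oracle", {
  gt <- annotation_set(data.frame(frame = 1L, r0 = 0, c0 = 0, r1 = 10, c1 = 10))
  one <- detections(data.frame(frame = 1L, r0 = 0, c0 = 0, r1 = 10, c1 = 10,
                               score = 0.7))
  expect_equal(average_precision(one, gt), 1.0)
  all_fp <- detections(data.frame(frame = 1L, r0 = 50, c0 = 50, r1 = 60,
                                  c1 = 60, score = c(0.9, 0.5)))
  expect_equal(average_precision(all_fp, gt), 0.0)
  expect_error(average_precision(one, annotation_set(one[0, 1:5])), "ground-truth")
  # deterministic 5-detections / 3-ground-truths fixture
  gts3 <- annotation_set(data.frame(frame = 1L,
                                    r0 = c(0, 0, 20), c0 = c(0, 20, 0),
                                    r1 = c(10, 10, 30), c1 = c(10, 30, 10)))
  dets5 <- detections(data.frame(
    frame = 1L,
    r0 = c(0, 1, 50, 20, 21), c0 = c(0, 21, 50, 1, 1),
    r1 = c(10, 11, 60, 30, 31), c1 = c(10, 31, 60, 11, 11),
    score = c(0.9, 0.8, 0.7, 0.6, 0.5)))
  expect_equal(average_precision(dets5, gts3),
               brute_ap_oracle(dets5, gts3), tolerance = 1e-4)
  # randomized small fixtures (<= 6 detections)
  for (seed in 1:8) {
    fx <- random_detection_fixture(seed, n_det = sample(2:6, 1),
                                   n_gt = sample(2:5, 1))
    expect_equal(average_precision(fx$dets, fx$gts),
                 brute_ap_oracle(fx$dets, fx$gts), tolerance = 1e-4)
  }
})

test_that("metrics are invariant to detection order at equal scores", {
  fx <- random_detection_fixture(42, n_det = 5, n_gt = 4)
  dets <- fx$dets
  dets$score <- rep(0.5, nrow(dets))  # all tied: frame/order tie-break applies
  ev1 <- evaluate_detections(detections(dets), fx$gts)
  perm <- c(3, 1, 5, 2, 4)
  dets2 <- detections(as.data.frame(dets)[perm, ])
  ev2 <- evaluate_detections(dets2, fx$gts)
  expect_equal(ev1$ap, ev2$ap)
  expect_equal(ev1$precision, ev2$precision)
  expect_equal(ev1$recall, ev2$recall)
})

test_that("oracle provider reproduces ground truth and degrades controllably", {
  scene <- generate_scene(small_scene_config(duration = 1))
  dets <- oracle_provider(scene$gt_masks)
  expect_true(all(dets$score == 1))
  ev <- evaluate_detections(dets, scene$gt_annotations)
  expect_equal(ev$precision, 1.0)
  expect_equal(ev$recall, 1.0)
  expect_equal(ev$ap, 1.0)
  expect_equal(ev$map, ev$ap)
  # mask IoU route agrees on the unperturbed oracle
  expect_equal(evaluate_detections(dets, scene$gt_annotations,
                                   use_mask = TRUE)$ap, 1.0)
  # dropping is seeded and deterministic
  d1 <- oracle_provider(scene$gt_masks, drop_rate = 0.5, seed = 3L)
  d2 <- oracle_provider(scene$gt_masks, drop_rate = 0.5, seed = 3L)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_lt(nrow(d1), nrow(dets))
})

test_that("heavy dilation pushes oracle detections below the IoU threshold", {
  cfg <- small_scene_config(duration = 0.3, nostril_radii = c(5, 4),
                            motion_amplitude = 0)
  scene <- generate_scene(cfg)
  big <- oracle_provider(scene$gt_masks, dilation = 6)
  # dilated ellipse IoU vs original: area ratio makes every match fail
  m <- match_detections(big, scene$gt_annotations, 0.5, use_mask = TRUE)
  expect_true(all(m$iou < 0.5))
  expect_identical(sum(m$tp), 0L)
  ev <- evaluate_detections(big, scene$gt_annotations, use_mask = TRUE)
  expect_equal(ev$precision, 0)  # every frame becomes an FP + FN pair
  expect_equal(ev$recall, 0)
})

test_that("the threshold detector recovers clean nostrils", {
  cfg <- small_scene_config(duration = 1, amplitude = 2)
  scene <- generate_scene(cfg)
  area <- sum(scene$gt_masks$frames[, , 1]) / 2
  dets <- threshold_detector(scene$thermal, min_area = area * 0.5,
                             max_area = area * 2)
  # exactly two components (nostrils) per frame within the area band
  expect_identical(nrow(dets), 2L * n_frames(scene$thermal))
  m <- match_detections(dets, scene$gt_annotations, 0.5, use_mask = TRUE)
  expect_true(all(m$iou >= 0.9))
  # featureless frames yield no detections
  flat <- thermal_sequence(array(25, c(20, 20, 2)), fps = 10)
  expect_identical(nrow(threshold_detector(flat, 5, 50)), 0L)
})
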