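#' Scored instance detections
#'
#' A set of per-frame detections, each a bounding box with a confidence
#' score and optionally an instance mask. Boxes use the package-wide
#' convention: 0-based, row-major, half-open `[r0, r1) x [c0, c1)` pixel
#' rectangles, so the box area in pixels is `(r1 - r0) * (c1 - c0)`.
#'
#' @param df Data frame with columns `frame` (1-based frame index), `r0`,
#'   `c0`, `r1`, `c1` and `score` in `[0, 1]`.
#' @param masks Optional list of `H x W` binary instance masks, one per row
#'   (entries may be `NULL`).
#' @return An object of class `detections` (a data frame with a `masks`
#'   attribute).
#' @export
detections <- function(df, masks = NULL) {
  need <- c("frame", "r0", "c0", "r1", "c1", "score")
  if (!all(need %in% names(df)))
    stop("detections need columns: ", paste(need, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[need]
  if (nrow(df)) {
    if (any(df$score < 0 | df$score > 1))
      stop("scores must lie in [0, 1]", call. = FALSE)
    check_boxes(df)
  }
  if (!is.null(masks) && length(masks) != nrow(df))
    stop("`masks` must have one entry per detection", call. = FALSE)
  rownames(df) <- NULL
  structure(df, masks = masks, class = c("detections", "data.frame"))
}

#' Ground-truth annotation set
#'
#' Per-frame ground-truth objects (boxes and optionally instance masks,
#' without scores), the reference against which detections are scored.
#' Same box convention as [detections()].
#'
#' @param df Data frame with columns `frame`, `r0`, `c0`, `r1`, `c1`.
#' @param masks Optional list of instance masks, one per row.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(df, masks = NULL) {
  need <- c("frame", "r0", "c0", "r1", "c1")
  if (!all(need %in% names(df)))
    stop("annotations need columns: ", paste(need, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[need]
  if (nrow(df)) check_boxes(df)
  if (!is.null(masks) && length(masks) != nrow(df))
    stop("`masks` must have one entry per annotation", call. = FALSE)
  rownames(df) <- NULL
  structure(df, masks = masks, class = c("annotation_set", "data.frame"))
}

check_boxes <- function(df) {
  if (any(df$r1 <= df$r0 | df$c1 <= df$c0))
    stop("degenerate box: half-open boxes need r1 > r0 and c1 > c0", call. = FALSE)
  invisible(TRUE)
}

#' Intersection over union of two boxes
#'
#' Overlap ratio `|a intersect b| / |a union b|` between two half-open pixel
#' rectangles `c(r0, c0, r1, c1)`; symmetric, in `[0, 1]`.
#'
#' @param a,b Boxes as length-4 numeric vectors `c(r0, c0, r1, c1)`.
#' @return IoU fraction in `[0, 1]`.
#' @examples
#' iou_box(c(0, 0, 10, 10), c(5, 5, 15, 15))  # 25 / 175
#' @export
iou_box <- function(a, b) {
  stopifnot(length(a) == 4L, length(b) == 4L)
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2])
    stop("degenerate (zero-area) box", call. = FALSE)
  ih <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iw <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ih * iw
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

#' Intersection over union of two binary masks
#' @param a,b Binary matrices of equal shape.
#' @return IoU fraction; errors if both masks are empty.
#' @export
iou_mask <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) stop("degenerate (empty) masks", call. = FALSE)
  sum(a & b) / u
}

# Order detections for matching/AP: descending score, ties broken by frame
# index, then box coordinates, then row order. Breaking ties on intrinsic
# box geometry (not input position) makes the metrics invariant to the
# order detections arrive in, even at equal scores.
detection_order <- function(dets) {
  order(-dets$score, dets$frame, dets$r0, dets$c0, dets$r1, dets$c1,
        seq_len(nrow(dets)))
}

#' Match detections to ground truth
#'
#' Greedy one-to-one matching in descending score order: each detection is
#' matched to the unmatched same-frame ground truth of highest IoU, and is a
#' true positive iff that IoU strictly exceeds `iou_threshold` ("exceeds
#' 50\%": at exactly the threshold a match fails). Each ground truth is
#' matched at most once. Score ties are broken by frame index, then box
#' coordinates, then detection order, so the result does not depend on the
#' order detections arrive in.
#'
#' @param dets A [detections()] object.
#' @param gts An [annotation_set()].
#' @param iou_threshold IoU threshold in (0, 1); default 0.5.
#' @param use_mask Match on instance-mask IoU instead of box IoU (both
#'   objects must carry masks).
#' @return Data frame, one row per detection in descending-score order:
#'   `det` (row in `dets`), `frame`, `score`, `tp`, `gt` (matched row in
#'   `gts` or `NA`), `iou`.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5, use_mask = FALSE) {
  stopifnot(inherits(dets, "detections"), inherits(gts, "annotation_set"))
  if (iou_threshold <= 0 || iou_threshold >= 1)
    stop("iou_threshold must be in (0, 1)", call. = FALSE)
  dmasks <- attr(dets, "masks"); gmasks <- attr(gts, "masks")
  if (use_mask && (is.null(dmasks) || is.null(gmasks)))
    stop("use_mask = TRUE requires instance masks on both sides", call. = FALSE)
  ord <- detection_order(dets)
  taken <- rep(FALSE, nrow(gts))
  out <- data.frame(det = ord, frame = dets$frame[ord],
                    score = dets$score[ord],
                    tp = rep(FALSE, length(ord)),
                    gt = rep(NA_integer_, length(ord)),
                    iou = rep(0, length(ord)))
  for (k in seq_along(ord)) {
    i <- ord[k]
    cand <- which(gts$frame == dets$frame[i] & !taken)
    if (!length(cand)) next
    ious <- vapply(cand, function(j) {
      if (use_mask) iou_mask(dmasks[[i]], gmasks[[j]])
      else iou_box(unlist(dets[i, c("r0", "c0", "r1", "c1")]),
                   unlist(gts[j, c("r0", "c0", "r1", "c1")]))
    }, numeric(1))
    best <- which.max(ious)
    out$iou[k] <- ious[best]
    if (ious[best] > iou_threshold) {
      out$tp[k] <- TRUE
      out$gt[k] <- cand[best]
      taken[cand[best]] <- TRUE
    }
  }
  out
}

#' Precision and recall from match counts
#'
#' Precision is the fraction of detections that are true (`tp / n_det`, 0 by
#' convention when there are no detections); recall is the fraction of ground
#' truths recovered (`tp / n_gt`).
#'
#' @param tp Number of true-positive detections.
#' @param n_det Total number of detections.
#' @param n_gt Total number of ground-truth objects (> 0).
#' @return Named numeric vector `c(precision = ..., recall = ...)`.
#' @examples
#' precision_recall(2, 3, 5)  # 2/3 and 2/5
#' @export
precision_recall <- function(tp, n_det, n_gt) {
  if (n_gt == 0) stop("recall undefined: no ground-truth objects", call. = FALSE)
  if (tp > min(n_det, n_gt)) stop("tp cannot exceed min(n_det, n_gt)", call. = FALSE)
  c(precision = if (n_det == 0) 0 else tp / n_det, recall = tp / n_gt)
}

#' Average precision at a fixed IoU threshold
#'
#' Detections are accumulated in descending score order into a
#' precision-recall curve, and AP is the all-point interpolated area under
#' it: precision is replaced by its running envelope (the maximum precision
#' at any recall at least as large) and integrated over recall. With a single
#' object class, mAP equals this AP.
#'
#' @inheritParams match_detections
#' @return AP fraction in `[0, 1]`.
#' @export
average_precision <- function(dets, gts, iou_threshold = 0.5, use_mask = FALSE) {
  n_gt <- nrow(gts)
  if (n_gt == 0) stop("AP undefined: no ground-truth objects", call. = FALSE)
  if (nrow(dets) == 0) return(0)
  m <- match_detections(dets, gts, iou_threshold, use_mask)
  cum_tp <- cumsum(m$tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / seq_along(cum_tp)
  envelope <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * envelope)
}

#' Score detections against ground truth
#'
#' Overall precision, recall and (m)AP of a detection set at one IoU
#' threshold. With a single class mAP equals AP.
#'
#' @inheritParams match_detections
#' @return An object of class `detection_evaluation`: list with `precision`,
#'   `recall`, `ap`, `map`, `iou_threshold`, `tp`, `n_det`, `n_gt`.
#' @export
evaluate_detections <- function(dets, gts, iou_threshold = 0.5,
                                use_mask = FALSE) {
  m <- match_detections(dets, gts, iou_threshold, use_mask)
  pr <- precision_recall(sum(m$tp), nrow(dets), nrow(gts))
  ap <- average_precision(dets, gts, iou_threshold, use_mask)
  structure(list(precision = unname(pr["precision"]),
                 recall = unname(pr["recall"]),
                 ap = ap, map = ap, iou_threshold = iou_threshold,
                 tp = sum(m$tp), n_det = nrow(dets), n_gt = nrow(gts)),
            class = "detection_evaluation")
}

#' @export
print.detection_evaluation <- function(x, ...) {
  cat(sprintf(
    "<detection_evaluation> IoU > %.2f: precision %.3f, recall %.3f, AP %.3f (mAP %.3f)\n",
    x$iou_threshold, x$precision, x$recall, x$ap, x$map))
  cat(sprintf("  %d TP of %d detections against %d ground truths\n",
              x$tp, x$n_det, x$n_gt))
  invisible(x)
}

# Component bounding boxes/masks of one labelled frame -> annotation rows.
components_to_objects <- function(lab, frame) {
  k <- max(lab)
  rows <- list(); masks <- list()
  for (j in seq_len(k)) {
    idx <- which(lab == j)
    ri <- ((idx - 1L) %% nrow(lab)) + 1L
    ci <- ((idx - 1L) %/% nrow(lab)) + 1L
    m <- matrix(0L, nrow(lab), ncol(lab)); m[idx] <- 1L
    rows[[j]] <- data.frame(frame = frame,
                            r0 = min(ri) - 1L, c0 = min(ci) - 1L,
                            r1 = max(ri), c1 = max(ci))
    masks[[j]] <- m
  }
  list(rows = rows, masks = masks)
}

#' Oracle mask provider
#'
#' Controlled stand-in for a trained instance detector: emits the
#' ground-truth objects themselves (scores fixed at 1.0), optionally dilated
#' by a disc of radius `dilation` pixels and randomly dropped per object with
#' probability `drop_rate`. Seeded and reproducible; with `dilation = 0` and
#' `drop_rate = 0` the detections coincide with the ground truth and score
#' AP = 1.
#'
#' @param gt_masks A [mask_sequence()] of ground-truth masks; per-frame
#'   8-connected components become individual objects.
#' @param dilation Disc radius in pixels for binary dilation (0 = none).
#' @param drop_rate Per-object drop probability in `[0, 1)`.
#' @param seed Integer seed for the drop draws.
#' @return A [detections()] object with instance masks.
#' @export
oracle_provider <- function(gt_masks, dilation = 0, drop_rate = 0, seed = 1L) {
  stopifnot(inherits(gt_masks, "mask_sequence"))
  if (drop_rate < 0 || drop_rate >= 1)
    stop("drop_rate must be in [0, 1)", call. = FALSE)
  brush <- if (dilation > 0) EBImage::makeBrush(2L * as.integer(dilation) + 1L,
                                                shape = "disc") else NULL
  rows <- list(); masks <- list(); n <- 0L
  for (t in seq_len(n_frames(gt_masks))) {
    fr <- gt_masks$frames[, , t]
    if (!is.null(brush)) fr <- (EBImage::dilate(fr, brush) != 0) * 1L
    lab <- label_components(fr)
    obj <- components_to_objects(lab, t)
    for (j in seq_along(obj$rows)) {
      n <- n + 1L
      rows[[n]] <- cbind(obj$rows[[j]], score = 1.0)
      masks[[n]] <- obj$masks[[j]]
    }
  }
  if (!n) return(detections(data.frame(frame = integer(), r0 = numeric(),
                                       c0 = numeric(), r1 = numeric(),
                                       c1 = numeric(), score = numeric())))
  df <- do.call(rbind, rows)
  keep <- with_local_seed(seed, stats::runif(n) >= drop_rate)
  detections(df[keep, , drop = FALSE], masks = masks[keep])
}

#' Classical threshold-based nose detector
#'
#' Dependency-light fallback detector operating on the thermal frames alone:
#' each frame is optimally quantized, supra-threshold pixels form the object
#' map, 8-connected components within an area band are emitted as detections,
#' and the confidence score is the component's mean quantized intensity / 255.
#' Frames that are constant (no thermal contrast) yield no detections.
#'
#' @param thermal A [thermal_sequence()].
#' @param min_area,max_area Component area bounds in pixels (`0 < min < max`).
#' @param n_bins Histogram bins for quantization.
#' @return A [detections()] object with instance masks.
#' @export
threshold_detector <- function(thermal, min_area, max_area, n_bins = 256) {
  stopifnot(inherits(thermal, "thermal_sequence"))
  if (min_area <= 0 || max_area <= min_area)
    stop("need 0 < min_area < max_area", call. = FALSE)
  rows <- list(); masks <- list(); n <- 0L
  for (t in seq_len(n_frames(thermal))) {
    fr <- thermal$frames[, , t]
    q <- tryCatch(optimal_quantize(fr, n_bins), error = function(e) NULL)
    if (is.null(q)) next  # constant frame: nothing to detect
    lab <- label_components(fr >= q$threshold)
    obj <- components_to_objects(lab, t)
    for (j in seq_along(obj$masks)) {
      area <- sum(obj$masks[[j]])
      if (area < min_area || area > max_area) next
      n <- n + 1L
      rows[[n]] <- cbind(obj$rows[[j]],
                         score = mean(q$pixels[obj$masks[[j]] == 1L]) / 255)
      masks[[n]] <- obj$masks[[j]]
    }
  }
  if (!n) return(detections(data.frame(frame = integer(), r0 = numeric(),
                                       c0 = numeric(), r1 = numeric(),
                                       c1 = numeric(), score = numeric())))
  detections(do.call(rbind, rows), masks = masks)
}
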