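#' Write a thermal sequence to a CSV frame directory
#'
#' The on-disk container is a directory of per-frame CSV matrices
#' (`frame_000001.csv`, one row per pixel row, no header) plus a
#' `sequence.json` sidecar recording `fps`, `emissivity`, `units` and the
#' declared shape. The round trip through [read_thermal_sequence()] is exact
#' to the numeric text precision used (17 significant digits, i.e. lossless
#' for doubles).
#'
#' @param seq A [thermal_sequence()].
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_thermal_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "thermal_sequence"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(seq$frames)
  meta <- list(fps = seq$fps, emissivity = seq$emissivity, units = seq$units,
               frames = d[3], height = d[1], width = d[2])
  jsonlite::write_json(meta, file.path(path, "sequence.json"),
                       auto_unbox = TRUE, digits = NA)
  for (t in seq_len(d[3])) {
    con <- file(file.path(path, sprintf("frame_%06d.csv", t)), "w")
    utils::write.table(format(seq$frames[, , t], digits = 17, trim = TRUE,
                              scientific = FALSE),
                       con, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    close(con)
  }
  invisible(path)
}

#' Read a thermal sequence from a CSV frame directory
#'
#' Counterpart of [write_thermal_sequence()]. The sidecar must declare `fps`;
#' the declared shape is checked against the loaded data, and every value is
#' validated against the device range -20..400 degC (a violation is reported
#' with its frame and pixel).
#'
#' @param path Directory written by [write_thermal_sequence()] (or assembled
#'   by hand: per-frame CSVs plus `sequence.json`).
#' @return A validated [thermal_sequence()].
#' @export
read_thermal_sequence <- function(path) {
  sidecar <- file.path(path, "sequence.json")
  if (!file.exists(sidecar))
    stop("format error: missing sequence.json sidecar in ", path, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fps))
    stop("format error: sidecar lacks fps metadata", call. = FALSE)
  files <- sort(list.files(path, pattern = "^frame_[0-9]+\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no frame CSV files found in ", path, call. = FALSE)
  if (!is.null(meta$frames) && length(files) != meta$frames)
    stop(sprintf("declared frame count %d but %d frame files present",
                 meta$frames, length(files)), call. = FALSE)
  frames <- NULL
  for (t in seq_along(files)) {
    m <- as.matrix(utils::read.table(files[t], sep = ",", header = FALSE))
    dimnames(m) <- NULL
    if (is.null(frames))
      frames <- array(NA_real_, dim = c(nrow(m), ncol(m), length(files)))
    if (!all(dim(m) == dim(frames)[1:2]))
      stop(sprintf("frame %d has shape %dx%d, expected %dx%d", t,
                   nrow(m), ncol(m), dim(frames)[1], dim(frames)[2]),
           call. = FALSE)
    frames[, , t] <- m
  }
  if (!is.null(meta$height) &&
      (dim(frames)[1] != meta$height || dim(frames)[2] != meta$width))
    stop("declared frame shape does not match frame files", call. = FALSE)
  thermal_sequence(frames, fps = meta$fps,
                   emissivity = if (is.null(meta$emissivity)) 0.95
                                else meta$emissivity)
}

#' Write a mask sequence as a PNG stack
#'
#' One 8-bit grayscale PNG per frame (`mask_000001.png`, ...), with mask
#' value 1 stored as 255 and 0 as 0. The round trip through
#' [read_mask_sequence()] is bit-exact.
#'
#' @param m A [mask_sequence()].
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_mask_sequence <- function(m, path) {
  stopifnot(inherits(m, "mask_sequence"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_len(n_frames(m)))
    png::writePNG(m$frames[, , t] * 1.0,
                  file.path(path, sprintf("mask_%06d.png", t)))
  invisible(path)
}

#' Read a mask sequence from a PNG stack
#'
#' Pixels must be exactly 0 or 255 in the PNG (0 or 1 after decoding); any
#' intermediate gray value is rejected as non-binary.
#'
#' @param path Directory of `mask_*.png` files.
#' @return A [mask_sequence()].
#' @export
read_mask_sequence <- function(path) {
  files <- sort(list.files(path, pattern = "^mask_[0-9]+\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no mask PNG files found in ", path, call. = FALSE)
  frames <- NULL
  for (t in seq_along(files)) {
    img <- png::readPNG(files[t])
    if (length(dim(img)) == 3L) img <- img[, , 1L]  # tolerate gray-as-RGB
    if (!all(img %in% c(0, 1)))
      stop(sprintf("non-binary mask pixel values in %s", basename(files[t])),
           call. = FALSE)
    if (is.null(frames))
      frames <- array(0L, dim = c(nrow(img), ncol(img), length(files)))
    frames[, , t] <- as.integer(img)
  }
  mask_sequence(frames)
}

#' Write an RGB sequence as a PNG frame directory
#' @param rgb An [rgb_sequence()].
#' @param path Directory to create/fill (`rgb_000001.png`, ...).
#' @return `path`, invisibly.
#' @export
write_rgb_sequence <- function(rgb, path) {
  stopifnot(inherits(rgb, "rgb_sequence"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_len(n_frames(rgb)))
    png::writePNG(rgb$frames[, , , t] / 255,
                  file.path(path, sprintf("rgb_%06d.png", t)))
  invisible(path)
}

#' Write detections or ground-truth annotations to JSON
#'
#' Schema: `{"frames": [{"index": <0-based frame>, "objects": [{"box":
#' [r0, c0, r1, c1], "score": <number, detections only>, "mask_ref":
#' <relative PNG path, optional>}]}]}`. Boxes are 0-based half-open pixel
#' rectangles. If the object carries instance masks and `masks_dir` is given,
#' each mask is written as a binary PNG next to the JSON and referenced.
#'
#' @param x A [detections()] or [annotation_set()] object.
#' @param path Output JSON file.
#' @param masks_dir Optional directory (relative to `dirname(path)`) for
#'   instance-mask PNGs.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(x, path, masks_dir = NULL) {
  stopifnot(inherits(x, "detections") || inherits(x, "annotation_set"))
  masks <- attr(x, "masks")
  has_score <- inherits(x, "detections")
  if (!is.null(masks_dir))
    dir.create(file.path(dirname(path), masks_dir),
               recursive = TRUE, showWarnings = FALSE)
  frames <- lapply(sort(unique(x$frame)), function(f) {
    rows <- which(x$frame == f)
    objects <- lapply(seq_along(rows), function(k) {
      i <- rows[k]
      obj <- list(box = c(x$r0[i], x$c0[i], x$r1[i], x$c1[i]))
      if (has_score) obj$score <- x$score[i]
      if (!is.null(masks_dir) && !is.null(masks) && !is.null(masks[[i]])) {
        ref <- file.path(masks_dir, sprintf("obj_%06d_%02d.png", f, k))
        png::writePNG(masks[[i]] * 1.0, file.path(dirname(path), ref))
        obj$mask_ref <- ref
      }
      obj
    })
    list(index = f - 1L, objects = objects)
  })
  jsonlite::write_json(list(frames = frames), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read detections or annotations from JSON
#'
#' @param path JSON file following the [write_annotations()] schema (the
#'   import route for masks produced by an external instance-segmentation
#'   system).
#' @param type `"detections"` (objects must carry scores) or `"annotations"`.
#' @return A [detections()] or [annotation_set()] object; `mask_ref` entries
#'   are resolved relative to the JSON file and loaded when present.
#' @export
read_annotations <- function(path, type = c("detections", "annotations")) {
  type <- match.arg(type)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- list(); masks <- list(); n <- 0L
  for (fr in doc$frames) {
    for (obj in fr$objects) {
      n <- n + 1L
      box <- unlist(obj$box)
      rows[[n]] <- data.frame(frame = fr$index + 1L, r0 = box[1], c0 = box[2],
                              r1 = box[3], c1 = box[4],
                              score = if (is.null(obj$score)) NA_real_
                                      else obj$score)
      masks[n] <- list(if (!is.null(obj$mask_ref)) {
        img <- png::readPNG(file.path(dirname(path), obj$mask_ref))
        if (length(dim(img)) == 3L) img <- img[, , 1L]
        matrix(as.integer(img), nrow(img), ncol(img))
      })
    }
  }
  df <- if (n) do.call(rbind, rows)
        else data.frame(frame = integer(), r0 = numeric(), c0 = numeric(),
                        r1 = numeric(), c1 = numeric(), score = numeric())
  if (all(vapply(masks, is.null, logical(1)))) masks <- NULL
  if (type == "detections") {
    if (n && anyNA(df$score))
      stop("detections JSON must carry a score for every object", call. = FALSE)
    detections(df, masks = masks)
  } else {
    annotation_set(df[setdiff(names(df), "score")], masks = masks)
  }
}

#' Write an ROI series to CSV
#'
#' Columns: `frame_index` (1-based), `time_s`, `value`, `pixel_count`.
#' Missing frames (empty masks) have empty `value` fields.
#'
#' @param series A [roi_series][extract_series()] object.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_roi_series <- function(series, path) {
  stopifnot(inherits(series, "roi_series"))
  df <- data.frame(frame_index = seq_along(series$values),
                   time_s = series$time,
                   value = series$values,
                   pixel_count = series$pixel_counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an ROI series from CSV
#' @param path CSV written by [write_roi_series()].
#' @param method Aggregation method label to attach (`"mean"`, `"max"`, `"sum"`).
#' @param fps Frame rate in frames per second.
#' @return A `roi_series` object.
#' @export
read_roi_series <- function(path, method, fps) {
  df <- utils::read.csv(path)
  new_roi_series(values = df$value, pixel_counts = df$pixel_count,
                 method = match.arg(method, c("mean", "max", "sum")),
                 fps = fps)
}
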