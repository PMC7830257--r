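#' Otsu threshold on a temperature collection
#'
#' Finds the temperature that best separates object (warm nose) from
#' background in a frame or recording by maximizing the between-class
#' variance of an `n_bins` histogram — the classical Otsu criterion for
#' "the threshold that best separates objects from background". Candidate
#' thresholds are the interior histogram bin edges; ties are broken toward
#' the lower threshold.
#'
#' @param values Numeric temperatures in degC (at least two distinct values).
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold temperature in degC: pixels `< threshold` are
#'   background, pixels `>= threshold` are object.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  lo <- min(values); hi <- max(values)
  if (!length(values) || lo == hi)
    stop("degenerate input: need at least two distinct values", call. = FALSE)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  edges <- seq(lo, hi, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  # cumulative class weights/means below each interior edge
  w0 <- cumsum(counts)[-n_bins]
  s0 <- cumsum(counts * mids)[-n_bins]
  n <- length(values); stot <- sum(counts * mids)
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (w0[valid] / n) * (w1[valid] / n) *
    (s0[valid] / w0[valid] - (stot - s0[valid]) / w1[valid])^2
  edges[which.max(bcv) + 1L]  # which.max takes the first (lowest) maximizer
}

#' Optimal quantization of a thermal frame
#'
#' Converts a temperature frame into a display image that separates object
#' from background and maximizes contrast: the frame is thresholded at
#' [otsu_threshold()] (or a caller-supplied threshold, e.g. one computed once
#' per recording), sub-threshold pixels map to intensity 0, and the
#' `[threshold, max]` temperature range maps linearly onto `[0, 255]`.
#'
#' @param frame Numeric `H x W` temperature matrix (non-constant).
#' @param n_bins Histogram bins for the threshold search.
#' @param threshold Optional fixed threshold in degC; `NULL` (default)
#'   computes it from this frame (dynamic, per-frame quantization).
#' @return An object of class `quantized_frame`: list with `pixels`
#'   (`H x W` intensities in `[0, 255]`) and `threshold` (degC).
#' @export
optimal_quantize <- function(frame, n_bins = 256, threshold = NULL) {
  stopifnot(is.matrix(frame))
  if (is.null(threshold)) threshold <- otsu_threshold(frame, n_bins)
  hi <- max(frame)
  if (hi <= threshold)
    stop("degenerate input: no pixels above threshold", call. = FALSE)
  px <- (frame - threshold) / (hi - threshold) * 255
  px[frame < threshold] <- 0
  structure(list(pixels = px, threshold = threshold),
            class = "quantized_frame")
}

#' Label connected components of a binary mask (8-connectivity)
#'
#' Components are labelled with `EBImage::bwlabel()` (4-connectivity) and
#' diagonally adjacent labels are then merged by union-find, giving standard
#' 8-connected components. Boundary-touching components are retained.
#'
#' @param mask Binary `H x W` matrix.
#' @return Integer `H x W` matrix of component labels (0 = background),
#'   relabelled consecutively from 1.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel((mask != 0) * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  k <- max(lab)
  if (k <= 1L) return(lab)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  H <- nrow(lab); W <- ncol(lab)
  # diagonal neighbour pairs: offsets (+1,+1) and (+1,-1)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-H, -1]), as.vector(lab[-1, -W])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  for (i in seq_len(nrow(pairs))) {
    a <- find(pairs[i, 1]); b <- find(pairs[i, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(k), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}
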