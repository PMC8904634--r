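# The ten per-frame descriptors and their per-video summaries, plus the
# augmentation transforms. Feature order is fixed and shared with the CSV
# feature-table layout.

ce_feature_names <- c("intensity_mean", "intensity_std", "red_mean",
                      "green_mean", "blue_mean", "sobel_sum", "crack_sum",
                      "entropy", "n_large_regions", "n_small_regions")

ce_stat_names <- c("mean", "std", "variation")

#' Names of the ten per-frame features
#' @return Character vector of length 10, in canonical order.
#' @export
feature_names <- function() ce_feature_names

#' Intensity and colour-channel statistics of a frame
#'
#' Mean and population standard deviation of the gray intensity plus the
#' per-channel means of R, G and B.
#'
#' @param frame RGB frame.
#' @return Named numeric vector `intensity_mean`, `intensity_std`,
#'   `red_mean`, `green_mean`, `blue_mean`.
#' @export
spectral_stats <- function(frame) {
  assert_frame(frame)
  g <- to_grayscale(frame)
  m <- mean(g)
  c(intensity_mean = m,
    intensity_std = sqrt(mean((g - m)^2)),
    red_mean = mean(frame[, , 1]),
    green_mean = mean(frame[, , 2]),
    blue_mean = mean(frame[, , 3]))
}

#' First-order histogram entropy of a gray image
#'
#' Shannon entropy `-sum(p * log2(p))` of the 256-bin gray-level histogram
#' (values quantized to the 8-bit grid), skipping empty bins. Ranges from 0
#' bits (constant image) to 8 bits (all 256 levels equiprobable).
#'
#' @param gray Gray matrix in `[0, 1]`.
#' @return Entropy in bits.
#' @export
frame_entropy <- function(gray) {
  assert_gray(gray)
  counts <- tabulate(as.integer(round(gray * 255)) + 1L, nbins = 256L)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Count the 1-pixels of a binary mask
#'
#' Applied to the contrast-windowed Sobel mask this is the edge-pixel sum;
#' applied to the crack-filter mask it is the non-crack tissue sum (high
#' values mean few cracks).
#'
#' @param mask 0/1 matrix.
#' @return Integer count.
#' @export
mask_pixel_sum <- function(mask) {
  assert_mask(mask)
  sum(mask == 1)
}

#' Fill the holes of a binary mask
#'
#' Background (0) components that do not touch the image border are interior
#' holes and are set to 1. Background connectivity is 4 (the topological
#' complement of 8-connected foreground).
#'
#' @param mask 0/1 matrix.
#' @return Mask with holes filled.
#' @export
fill_holes <- function(mask) {
  assert_mask(mask)
  inv <- matrix(1L - as.integer(mask), nrow(mask))
  lab <- cc_label_cpp(inv, 4L)
  if (max(lab) == 0L) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  hole <- setdiff(seq_len(max(lab)), c(0L, border))
  out <- matrix(as.integer(mask), nrow(mask))
  if (length(hole)) out[lab %in% hole] <- 1L
  out
}

#' Count large and small regions of an edge mask
#'
#' Each 8-connected component has its holes filled, then components are
#' counted by area: large ones at or above `area_threshold` (walls of the
#' intestine between folds), and small ones between `min_area` and the
#' threshold (residual fragments, plentiful on cracked mucosa).
#'
#' @param mask 0/1 matrix (normally the [modified_sobel()] output).
#' @param area_threshold Minimum area, in pixels, of a "large" region.
#'   Default 1000.
#' @param min_area Minimum area of a "small" region, excluding single-pixel
#'   noise. Default 10.
#' @return Named integer vector `n_large`, `n_small`.
#' @export
count_regions <- function(mask, area_threshold = 1000, min_area = 10) {
  assert_mask(mask)
  filled <- fill_holes(mask)
  lab <- cc_label_cpp(filled, 8L)
  n <- max(lab)
  if (n == 0L) return(c(n_large = 0L, n_small = 0L))
  areas <- tabulate(lab[lab > 0L], nbins = n)
  c(n_large = sum(areas >= area_threshold),
    n_small = sum(areas >= min_area & areas < area_threshold))
}

#' Compute the ten per-frame features
#'
#' Composition of the spectral statistics, histogram entropy, the two filter
#' masks' pixel sums, and the region counts, on a preprocessed frame.
#'
#' @param frame RGB frame (already preprocessed: text removed, border
#'   cropped), at least 3x3.
#' @param area_threshold,min_area Region-count parameters, see
#'   [count_regions()].
#' @param crack_threshold Crack-filter threshold on the 8-bit scale.
#' @param contrast_k Contrast window half-width for the Sobel composite.
#' @param crack_kernel 3x3 crack kernel override.
#' @return Named numeric vector of length 10 (see [feature_names()]).
#' @export
frame_features <- function(frame, area_threshold = 1000, min_area = 10,
                           crack_threshold = 5, contrast_k = 0.2,
                           crack_kernel = celiascope::crack_kernel()) {
  assert_frame(frame, min_dim = 3L)
  g <- to_grayscale(frame)
  ss <- spectral_stats(frame)
  edge_mask <- modified_sobel(g, k = contrast_k)
  crack_mask <- crack_response(g, kernel = crack_kernel,
                               threshold = crack_threshold)
  rc <- count_regions(edge_mask, area_threshold = area_threshold,
                      min_area = min_area)
  out <- c(ss,
           sobel_sum = mask_pixel_sum(edge_mask),
           crack_sum = mask_pixel_sum(crack_mask),
           entropy = frame_entropy(g),
           n_large_regions = unname(rc["n_large"]),
           n_small_regions = unname(rc["n_small"]))
  out[ce_feature_names]
}

#' Summarize per-frame features over a video
#'
#' For each of the ten features computes the mean, the population standard
#' deviation, and the variation (= variance, the squared standard deviation)
#' across the frames of one video.
#'
#' @param frames_features Matrix or data frame with one row per frame and the
#'   ten feature columns, or a list of [frame_features()] vectors.
#' @return Named numeric vector of length 30:
#'   `<feature>_mean`, `<feature>_std`, `<feature>_variation` per feature.
#' @export
summarize_video <- function(frames_features) {
  if (is.list(frames_features) && !is.data.frame(frames_features))
    frames_features <- do.call(rbind, frames_features)
  x <- as.matrix(frames_features)
  if (nrow(x) < 2)
    stop("need at least 2 frames to summarize a video", call. = FALSE)
  if (!is.null(colnames(x))) {
    if (!all(ce_feature_names %in% colnames(x)))
      stop("feature columns missing: expected the 10 canonical features",
           call. = FALSE)
    x <- x[, ce_feature_names, drop = FALSE]
  } else if (ncol(x) == length(ce_feature_names)) {
    colnames(x) <- ce_feature_names
  } else {
    stop("cannot identify the 10 feature columns", call. = FALSE)
  }
  m <- colMeans(x)
  v <- pmax(colMeans(x^2) - m^2, 0)
  s <- sqrt(v)
  out <- as.vector(rbind(m, s, v))
  names(out) <- as.vector(t(outer(ce_feature_names, ce_stat_names, paste,
                                  sep = "_")))
  out
}

#' Geometric frame augmentations
#'
#' Rotations by multiples of 90 degrees, horizontal/vertical mirroring, and
#' central zoom (crop the central `1/factor` window, then rescale back to the
#' original size by nearest-neighbour sampling). Rotating a non-square frame
#' by 90/270 degrees returns the transposed (`W x H`) geometry; all features
#' are dimension-agnostic.
#'
#' @param frame RGB frame.
#' @param op One of `"rotate90"`, `"rotate180"`, `"rotate270"`,
#'   `"mirror_h"`, `"mirror_v"`, `"zoom"`.
#' @param factor Zoom factor in `[1, 2]` (1 is the identity); required for
#'   `op = "zoom"`.
#' @return Transformed frame.
#' @export
augment_frame <- function(frame, op = c("rotate90", "rotate180", "rotate270",
                                        "mirror_h", "mirror_v", "zoom"),
                          factor = NULL) {
  assert_frame(frame)
  op <- match.arg(op)
  h <- dim(frame)[1]; w <- dim(frame)[2]
  rot90cw <- function(m) t(m[h:1, , drop = FALSE])
  per_channel <- function(f, dh, dw) {
    out <- array(0, dim = c(dh, dw, 3))
    for (ch in 1:3) out[, , ch] <- f(frame[, , ch])
    out
  }
  switch(op,
    rotate90 = per_channel(rot90cw, w, h),
    rotate180 = frame[h:1, w:1, , drop = FALSE],
    rotate270 = per_channel(function(m) t(m)[w:1, , drop = FALSE], w, h),
    mirror_h = frame[, w:1, , drop = FALSE],
    mirror_v = frame[h:1, , , drop = FALSE],
    zoom = {
      if (is.null(factor) || !is.numeric(factor) || length(factor) != 1 ||
          factor < 1 || factor > 2)
        stop("zoom `factor` must be a scalar in [1, 2]", call. = FALSE)
      hc <- max(1L, round(h / factor)); wc <- max(1L, round(w / factor))
      r0 <- floor((h - hc) / 2); c0 <- floor((w - wc) / 2)
      crop <- frame[r0 + (1:hc), c0 + (1:wc), , drop = FALSE]
      ri <- round(seq(1, hc, length.out = h))
      ci <- round(seq(1, wc, length.out = w))
      crop[ri, ci, , drop = FALSE]
    })
}
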