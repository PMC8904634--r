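# Frame cleaning: grayscale conversion, binarization, connected regions,
# overlay-text removal by border-band centroid filtering, and black-border
# cropping. These run before any feature computation.

#' Convert an RGB frame to a gray intensity image
#'
#' Uses the ITU-R BT.601 luminance weights (0.299, 0.587, 0.114).
#'
#' @param frame An `H x W x 3` frame array with values in `[0, 1]`.
#' @return An `H x W` matrix of gray intensities in `[0, 1]`.
#' @export
to_grayscale <- function(frame) {
  assert_frame(frame)
  g <- 0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
  clip01(g)
}

#' Otsu's histogram threshold
#'
#' Maximizes the between-class variance of the 256-bin gray-level histogram.
#' Returns a threshold on the `[0, 1]` scale placed halfway between the two
#' bins it separates; a constant image yields a threshold equal to its value,
#' so `gray > otsu_threshold(gray)` is then all-`FALSE`.
#'
#' @param gray Gray matrix in `[0, 1]`.
#' @return Scalar threshold in `[0, 1]`.
#' @export
otsu_threshold <- function(gray) {
  assert_gray(gray)
  counts <- tabulate(as.integer(round(gray * 255)) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)                 # P(class 0) for cut after bin t-1
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  t_idx <- 1:255
  w0 <- omega[t_idx]
  valid <- w0 > 0 & w0 < 1
  if (!any(valid)) return((which(counts > 0)[1] - 1L) / 255)
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[t_idx][valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  t_star <- which.max(sigma_b)       # cut between bins t_star-1 and t_star
  (t_star - 0.5) / 255
}

#' Binarize a gray image
#'
#' @param gray Gray matrix in `[0, 1]`.
#' @param threshold Scalar in `[0, 1]`, or `"auto"` for Otsu's threshold.
#' @return Integer 0/1 mask; pixel is 1 iff its value exceeds the threshold.
#' @export
binarize <- function(gray, threshold = "auto") {
  assert_gray(gray)
  if (identical(threshold, "auto")) {
    threshold <- otsu_threshold(gray)
  } else {
    if (!is.numeric(threshold) || length(threshold) != 1 ||
        is.na(threshold) || threshold < 0 || threshold > 1)
      stop("`threshold` must be a scalar in [0, 1] or \"auto\"", call. = FALSE)
  }
  m <- matrix(0L, nrow(gray), ncol(gray))
  m[gray > threshold] <- 1L
  m
}

#' Label connected regions of a binary mask
#'
#' 8-connected components of the 1-pixels, labeled 1..n in raster order.
#'
#' @param mask 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return A `data.frame` with one row per region: `region`, `area`,
#'   `centroid_r`, `centroid_c` (1-based pixel coordinates). The full label
#'   matrix is attached as attribute `"labels"`.
#' @export
label_regions <- function(mask, connectivity = 8L) {
  assert_mask(mask)
  lab <- cc_label_cpp(matrix(as.integer(mask), nrow(mask)), as.integer(connectivity))
  n <- max(lab)
  if (n == 0L) {
    out <- data.frame(region = integer(), area = integer(),
                      centroid_r = numeric(), centroid_c = numeric())
    attr(out, "labels") <- lab
    return(out)
  }
  idx <- which(lab > 0L)
  lv <- lab[idx]
  r <- ((idx - 1L) %% nrow(mask)) + 1L
  c <- ((idx - 1L) %/% nrow(mask)) + 1L
  area <- tabulate(lv, nbins = n)
  sums <- rowsum(cbind(r, c), lv)
  out <- data.frame(region = seq_len(n), area = area,
                    centroid_r = sums[, 1] / area, centroid_c = sums[, 2] / area)
  attr(out, "labels") <- lab
  out
}

#' Erase overlay text from a frame
#'
#' Capsule recorders stamp timestamps and device info near the frame edges.
#' The frame is converted to gray, auto-binarized, and its non-black regions
#' labeled; every region whose centroid falls inside the outer border band
#' (within `border_fraction` of the height from top/bottom, or of the width
#' from left/right) is erased by zeroing its pixels in all channels. Central
#' regions (the mucosa field) are untouched. Idempotent.
#'
#' @param frame RGB frame.
#' @param border_fraction Band width as a fraction of each dimension,
#'   in (0, 0.5). Default 0.2 (the outer 20 per cent).
#' @return Frame with border-band regions zeroed.
#' @export
remove_overlay_text <- function(frame, border_fraction = 0.2) {
  assert_frame(frame)
  if (!is.numeric(border_fraction) || length(border_fraction) != 1 ||
      border_fraction <= 0 || border_fraction >= 0.5)
    stop("`border_fraction` must lie in (0, 0.5)", call. = FALSE)
  h <- dim(frame)[1]; w <- dim(frame)[2]
  regs <- label_regions(binarize(to_grayscale(frame), "auto"))
  if (nrow(regs) == 0L) return(frame)
  in_band <- regs$centroid_r < border_fraction * h |
    regs$centroid_r > (1 - border_fraction) * h |
    regs$centroid_c < border_fraction * w |
    regs$centroid_c > (1 - border_fraction) * w
  kill <- regs$region[in_band]
  if (length(kill) == 0L) return(frame)
  lab <- attr(regs, "labels")
  idx <- which(matrix(lab %in% kill, h, w))
  npix <- h * w
  frame[c(idx, idx + npix, idx + 2L * npix)] <- 0
  frame
}

#' Crop the black border of a frame
#'
#' Returns the sub-frame spanned by the tight bounding box of pixels that are
#' non-zero in any channel (first/last non-zero row and column, inclusive) --
#' equivalent to scanning inward along width and length until a non-black
#' value is met.
#'
#' @param frame RGB frame with at least one non-zero pixel.
#' @return Cropped frame.
#' @export
crop_black_border <- function(frame) {
  assert_frame(frame)
  nz <- frame[, , 1] > 0 | frame[, , 2] > 0 | frame[, , 3] > 0
  rows <- which(rowSums(nz) > 0)
  cols <- which(colSums(nz) > 0)
  if (length(rows) == 0L)
    stop("cannot crop an all-black frame", call. = FALSE)
  frame[rows[1]:rows[length(rows)], cols[1]:cols[length(cols)], , drop = FALSE]
}

#' Full frame preprocessing
#'
#' Overlay-text removal followed by black-border cropping; the form every
#' frame takes before feature extraction.
#'
#' @inheritParams remove_overlay_text
#' @return Cleaned, cropped frame.
#' @export
preprocess_frame <- function(frame, border_fraction = 0.2) {
  crop_black_border(remove_overlay_text(frame, border_fraction))
}
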