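# The filter bank: generic 3x3 convolution, Sobel gradient magnitude, the
# narrow mean +/- k*sd contrast window, the contrast-windowed Sobel composite
# that isolates fold edges, and the hand-designed crack-detection kernel.

#' The Sobel kernel pair
#'
#' The horizontal-gradient core and its 90-degree rotation.
#'
#' @return List with 3x3 matrices `gx` and `gy`.
#' @export
sobel_kernels <- function() {
  gx <- matrix(c(1, 0, -1,
                 2, 0, -2,
                 1, 0, -1), nrow = 3, byrow = TRUE)
  gy <- matrix(c( 1,  2,  1,
                  0,  0,  0,
                 -1, -2, -1), nrow = 3, byrow = TRUE)
  list(gx = gx, gy = gy)
}

#' The crack-detection kernel
#'
#' Hand-designed 3x3 kernel whose centre weight amplifies a pixel while the
#' negative ring suppresses bright neighbours, so thin dark depressions
#' ("cracks", reminiscent of dry land) fall below a small threshold while
#' ordinary mucosa stays above it. Row-major coefficients
#' A..I = (-2.3, -1, -0.3, -1.4, 7.8, -1.4, -0.3, -1, 0); their sum is 0.1,
#' so a constant 8-bit image of value c responds with 0.1 * c.
#'
#' @return 3x3 numeric matrix.
#' @export
crack_kernel <- function() {
  matrix(c(-2.3, -1.0, -0.3,
           -1.4,  7.8, -1.4,
           -0.3, -1.0,  0.0), nrow = 3, byrow = TRUE)
}

#' Build a 3x3 kernel from named coefficients
#'
#' Accepts a list (e.g. parsed from JSON configuration) with fields
#' `A`..`I`, laid out row-major: A B C / D E F / G H I.
#'
#' @param coef Named list or vector with entries `A`..`I`.
#' @return 3x3 numeric matrix.
#' @export
kernel_from_coef <- function(coef) {
  need <- LETTERS[1:9]
  if (!all(need %in% names(coef)))
    stop("kernel coefficients must be named A..I", call. = FALSE)
  v <- vapply(need, function(n) as.numeric(coef[[n]]), numeric(1))
  if (any(!is.finite(v)))
    stop("kernel coefficients must be finite", call. = FALSE)
  matrix(v, nrow = 3, byrow = TRUE)
}

assert_kernel <- function(k) {
  if (!is.matrix(k) || !identical(dim(k), c(3L, 3L)) || !is.numeric(k) ||
      any(!is.finite(k)))
    stop("kernel must be a finite 3x3 numeric matrix", call. = FALSE)
  invisible(k)
}

#' Discrete 2-D convolution with a 3x3 kernel
#'
#' True convolution (the kernel is flipped relative to cross-correlation),
#' evaluated at every pixel with mirror boundary handling (the row/column
#' beyond an edge reflects to the one inside it, edge row not repeated).
#' Output values may be negative.
#'
#' @param gray Numeric matrix, at least 3x3 (values need not be in `[0,1]`).
#' @param kernel 3x3 numeric matrix.
#' @return Numeric matrix of the same dimensions as `gray`.
#' @export
convolve2d <- function(gray, kernel) {
  if (!is.matrix(gray) || !is.numeric(gray) || nrow(gray) < 3 || ncol(gray) < 3)
    stop("`gray` must be a numeric matrix of at least 3 x 3", call. = FALSE)
  assert_kernel(kernel)
  h <- nrow(gray); w <- ncol(gray)
  kf <- kernel[3:1, 3:1, drop = FALSE]        # flip -> correlate
  pad <- gray[c(2L, 1:h, h - 1L), c(2L, 1:w, w - 1L)]
  out <- matrix(0, h, w)
  for (a in 1:3) for (b in 1:3) {
    if (kf[a, b] == 0) next
    out <- out + kf[a, b] * pad[(a - 1L) + (1:h), (b - 1L) + (1:w)]
  }
  out
}

#' Sobel gradient magnitude
#'
#' `sqrt(Gx^2 + Gy^2)` pixel-wise, with `Gx`, `Gy` the convolutions of the
#' image with the two Sobel cores.
#'
#' @param gray Gray matrix, at least 3x3.
#' @return Non-negative matrix of gradient magnitudes.
#' @export
sobel_magnitude <- function(gray) {
  k <- sobel_kernels()
  gx <- convolve2d(gray, k$gx)
  gy <- convolve2d(gray, k$gy)
  sqrt(gx^2 + gy^2)
}

#' Contrast windowing around the image mean
#'
#' Rescales the narrow window `[mean - k*sd, mean + k*sd]` linearly onto
#' `[0, 1]`, clipping values outside it. With the default `k = 0.2` almost
#' every pixel saturates to 0 or 1, which flattens wall texture and leaves
#' fold boundaries as the dominant gradients for the Sobel stage.
#' A constant image (zero standard deviation) maps to all-0.5.
#'
#' @param gray Gray matrix in `[0, 1]`.
#' @param k Window half-width in units of the (population) standard
#'   deviation. Default 0.2.
#' @return Gray matrix in `[0, 1]`.
#' @export
adjust_contrast_window <- function(gray, k = 0.2) {
  assert_gray(gray)
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k <= 0)
    stop("`k` must be a positive scalar", call. = FALSE)
  m <- mean(gray)
  s <- sqrt(mean((gray - m)^2))
  if (s < 1e-12) return(matrix(0.5, nrow(gray), ncol(gray)))
  clip01((gray - (m - k * s)) / (2 * k * s))
}

#' Contrast-windowed Sobel edge mask
#'
#' The fold-detection composite: contrast windowing, Sobel magnitude,
#' rescaling by the maximum, then binarization. The resulting mask marks
#' fold/edge pixels.
#'
#' @param gray Gray matrix in `[0, 1]`, at least 3x3.
#' @param binarize_threshold Threshold for the final binarization of the
#'   max-normalized magnitude; `"auto"` (Otsu) by default.
#' @param k Contrast window half-width passed to [adjust_contrast_window()].
#' @return 0/1 mask of edge pixels.
#' @export
modified_sobel <- function(gray, binarize_threshold = "auto", k = 0.2) {
  assert_gray(gray, min_dim = 3L)
  mag <- sobel_magnitude(adjust_contrast_window(gray, k))
  mx <- max(mag)
  if (mx <= 0) return(matrix(0L, nrow(gray), ncol(gray)))
  binarize(mag / mx, binarize_threshold)
}

#' Crack-detection filter
#'
#' Convolves the image (taken to the 0-255 scale: the printed threshold is
#' only meaningful on 8-bit values) with the crack kernel and thresholds the
#' response. Pixels at or above the threshold are ordinary intestine tissue
#' (mask 1); pixels below are cracks (mask 0) -- so a *high* mask pixel sum
#' means *few* cracks.
#'
#' @param gray Gray matrix in `[0, 1]`, at least 3x3.
#' @param kernel 3x3 kernel; defaults to [crack_kernel()].
#' @param threshold Response threshold on the 8-bit scale. Default 5.
#' @param binarize If `FALSE`, return the signed 8-bit-scale response
#'   instead of the mask.
#' @return 0/1 mask (or the signed response matrix).
#' @export
crack_response <- function(gray, kernel = crack_kernel(), threshold = 5,
                           binarize = TRUE) {
  assert_gray(gray, min_dim = 3L)
  resp <- convolve2d(gray * 255, kernel)
  if (!binarize) return(resp)
  m <- matrix(0L, nrow(gray), ncol(gray))
  m[resp >= threshold] <- 1L
  m
}
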