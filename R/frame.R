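# Core rasters. A Frame is a plain H x W x 3 numeric array with channel values
# in [0, 1] (8-bit inputs divided by 255); a gray frame is an H x W matrix in
# [0, 1]; a binary mask is an H x W matrix of exactly 0/1. Plain base arrays
# keep every image operation composable with ordinary matrix code.

#' Test whether an object is a valid RGB frame
#'
#' A frame is an `H x W x 3` numeric array with all values in `[0, 1]`.
#'
#' @param x Object to test.
#' @return `TRUE` or `FALSE`.
#' @export
is_frame <- function(x) {
  is.array(x) && is.numeric(x) && length(dim(x)) == 3L && dim(x)[3] == 3L &&
    all(is.finite(x)) && min(x) >= 0 && max(x) <= 1
}

# min_dim: most ops accept any non-empty raster; 3x3 filtering needs >= 3.
assert_frame <- function(x, min_dim = 1L, arg = "frame") {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L || !is.numeric(x))
    stop(sprintf("`%s` must be an H x W x 3 numeric array", arg), call. = FALSE)
  d <- dim(x)
  if (d[1] < min_dim || d[2] < min_dim)
    stop(sprintf("`%s` must be at least %d x %d pixels", arg, min_dim, min_dim),
         call. = FALSE)
  if (anyNA(x) || min(x) < 0 || max(x) > 1)
    stop(sprintf("`%s` must have all channel values in [0, 1]", arg),
         call. = FALSE)
  invisible(x)
}

assert_gray <- function(x, min_dim = 1L, arg = "gray") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (nrow(x) < min_dim || ncol(x) < min_dim)
    stop(sprintf("`%s` must be at least %d x %d pixels", arg, min_dim, min_dim),
         call. = FALSE)
  if (anyNA(x) || min(x) < 0 || max(x) > 1)
    stop(sprintf("`%s` must have values in [0, 1]", arg), call. = FALSE)
  invisible(x)
}

assert_mask <- function(x, arg = "mask") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (anyNA(x) || !all(x == 0 | x == 1))
    stop(sprintf("`%s` must contain only 0 and 1", arg), call. = FALSE)
  invisible(x)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Build an RGB frame from a single gray matrix or constant colour
#'
#' Convenience constructor used heavily in tests and the synthetic generator.
#'
#' @param h,w Frame height and width in pixels.
#' @param rgb Length-3 colour in `[0, 1]` replicated over all pixels.
#' @return An `h x w x 3` frame array.
#' @export
solid_frame <- function(h, w, rgb = c(0, 0, 0)) {
  stopifnot(h >= 1, w >= 1, length(rgb) == 3, all(rgb >= 0), all(rgb <= 1))
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

#' Stack a gray image into a 3-channel frame
#'
#' @param gray Numeric matrix in `[0, 1]`.
#' @return Frame with all three channels equal to `gray`.
#' @export
gray_frame <- function(gray) {
  assert_gray(gray)
  array(rep(gray, 3), dim = c(nrow(gray), ncol(gray), 3))
}
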