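# Frame I/O. PNG and JPEG via the png/jpeg codecs; PPM/PGM (both ASCII and
# binary) supported as a plain-text-capable interchange format. A video is a
# directory of lexicographically ordered frame files.

#' Read a frame from disk
#'
#' Supports 8-bit PNG (`.png`), JPEG (`.jpg`/`.jpeg`) and portable pixmaps
#' (`.ppm`, `.pgm`, ASCII P2/P3 or binary P5/P6). Gray images are replicated
#' to 3 channels; an alpha channel is dropped.
#'
#' @param path Image file path.
#' @return An `H x W x 3` frame with values in `[0, 1]`.
#' @export
read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    ppm = ,
    pgm = read_pnm(path),
    stop(sprintf("unsupported image format: .%s", ext), call. = FALSE))
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] >= 4) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] != 3) stop("unsupported channel layout", call. = FALSE)
  clip01(img)
}

#' Write a frame to disk
#'
#' Format chosen by extension: PNG, JPEG, or PPM (binary P6, or ASCII P3
#' with `ascii = TRUE`).
#'
#' @param frame RGB frame in `[0, 1]`.
#' @param path Output path.
#' @param ascii For `.ppm`: write ASCII (P3) instead of binary (P6).
#' @export
write_frame <- function(frame, path, ascii = FALSE) {
  assert_frame(frame)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(frame, path),
    jpg = ,
    jpeg = jpeg::writeJPEG(frame, path, quality = 0.95),
    ppm = write_ppm(frame, path, ascii = ascii),
    stop(sprintf("unsupported image format: .%s", ext), call. = FALSE))
  invisible(path)
}

# ---- portable anymap --------------------------------------------------------

read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("not a supported PNM file", call. = FALSE)
  # header tokens: width, height, maxval; '#' comments allowed
  tokens <- integer(0)
  buf <- character(0)
  while (length(tokens) < 3) {
    ch <- readChar(con, 1)
    if (length(ch) == 0) stop("truncated PNM header", call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1)
        if (length(ch) == 0 || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf)) {
      tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    as.integer(readBin(con, "raw", n))
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) < n) stop("truncated PNM data", call. = FALSE)
  # PNM is row-major, channel-interleaved
  if (nch == 3L) {
    a <- array(vals / maxval, dim = c(3, w, h))
    aperm(a, c(3, 2, 1))
  } else {
    m <- t(matrix(vals / maxval, w, h))
    array(rep(m, 3), dim = c(h, w, 3))
  }
}

write_ppm <- function(frame, path, ascii = FALSE) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  vals <- as.integer(round(aperm(frame, c(3, 2, 1)) * 255))
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P3", paste(w, h), "255"), con)
    writeLines(paste(vals, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(vals), con)
  }
  invisible(path)
}

#' List the frame files of a video directory
#'
#' @param dir Directory holding one video's frames.
#' @return Lexicographically sorted paths of recognized image files.
#' @export
list_frame_files <- function(dir) {
  sort(list.files(dir, pattern = "\\.(png|jpe?g|ppm|pgm)$", full.names = TRUE,
                  ignore.case = TRUE))
}

#' Read a video (directory of frames)
#'
#' Unreadable frames are skipped with a warning.
#'
#' @param dir Video directory.
#' @return List of frames.
#' @export
read_video <- function(dir) {
  files <- list_frame_files(dir)
  frames <- lapply(files, function(f) {
    tryCatch(read_frame(f), error = function(e) {
      warning(sprintf("skipping unreadable frame %s: %s",
                      basename(f), conditionMessage(e)), call. = FALSE)
      NULL
    })
  })
  frames[!vapply(frames, is.null, logical(1))]
}
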