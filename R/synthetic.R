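# Seeded synthetic capsule-endoscopy frames: a roughly circular bright mucosa
# field on a black background, smooth colour texture, bright fold ridges, dark
# crack polylines (denser in the celiac phenotype), and an optional white
# timestamp-like overlay near a corner. Every preprocessing and filtering
# stage of the pipeline has something real to bite on, without patient data.

# 3 x 5 bitmap glyphs for the timestamp overlay (no font dependency).
ce_font <- list(
  "0" = c("111", "101", "101", "101", "111"),
  "1" = c("010", "110", "010", "010", "111"),
  "2" = c("111", "001", "111", "100", "111"),
  "3" = c("111", "001", "111", "001", "111"),
  "4" = c("101", "101", "111", "001", "001"),
  "5" = c("111", "100", "111", "001", "111"),
  "6" = c("111", "100", "111", "101", "111"),
  "7" = c("111", "001", "010", "010", "010"),
  "8" = c("111", "101", "111", "101", "111"),
  "9" = c("111", "101", "111", "001", "111"),
  ":" = c("000", "010", "000", "010", "000")
)

#' Phenotype parameters of the synthetic frame generator
#'
#' Class defaults mirror the published per-class channel means (healthy
#' mucosa redder than celiac) and the qualitative celiac artefacts: fewer
#' folds, many more cracks. All parameters can be overridden.
#'
#' @param label `"healthy"` or `"celiac"`.
#' @param base_rgb_mean Length-3 base mucosa colour in `[0, 1]`.
#' @param base_rgb_noise_std Standard deviation of the smooth colour texture.
#' @param n_folds Number of bright ridge arcs per frame.
#' @param fold_brightness Brightness added on fold ridges.
#' @param crack_density Poisson mean of the number of dark crack polylines.
#' @param crack_darkness Multiplicative darkening of crack pixels, in
#'   `[0, 1]` (0.1 = cracks at a tenth of local brightness).
#' @param field_radius_fraction Mucosa disk radius as a fraction of the
#'   inscribed-circle radius, in `(0, 1]`.
#' @param overlay_text Render a white timestamp block near the top-left
#'   corner.
#' @param frame_size Length-2 integer `(H, W)`.
#' @return A `phenotype_params` list.
#' @export
phenotype_params <- function(label = c("healthy", "celiac"),
                             base_rgb_mean = NULL,
                             base_rgb_noise_std = NULL,
                             n_folds = NULL,
                             fold_brightness = 0.15,
                             crack_density = NULL,
                             crack_darkness = 0.1,
                             field_radius_fraction = 0.8,
                             overlay_text = TRUE,
                             frame_size = c(128L, 128L)) {
  label <- match.arg(label)
  defaults <- if (label == "healthy") {
    list(base_rgb_mean = c(0.4265, 0.2914, 0.1551),
         base_rgb_noise_std = 0.08, n_folds = 6L, crack_density = 1)
  } else {
    list(base_rgb_mean = c(0.3340, 0.2749, 0.1654),
         base_rgb_noise_std = 0.10, n_folds = 2L, crack_density = 12)
  }
  p <- list(label = label,
            base_rgb_mean = base_rgb_mean %||% defaults$base_rgb_mean,
            base_rgb_noise_std = base_rgb_noise_std %||% defaults$base_rgb_noise_std,
            n_folds = n_folds %||% defaults$n_folds,
            fold_brightness = fold_brightness,
            crack_density = crack_density %||% defaults$crack_density,
            crack_darkness = crack_darkness,
            field_radius_fraction = field_radius_fraction,
            overlay_text = isTRUE(overlay_text),
            frame_size = as.integer(frame_size))
  stopifnot(length(p$base_rgb_mean) == 3, all(p$base_rgb_mean >= 0),
            all(p$base_rgb_mean <= 1), p$base_rgb_noise_std >= 0,
            p$n_folds >= 0, p$crack_density >= 0,
            p$crack_darkness >= 0, p$crack_darkness <= 1,
            p$field_radius_fraction > 0, p$field_radius_fraction <= 1,
            length(p$frame_size) == 2, all(p$frame_size >= 16))
  structure(p, class = "phenotype_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Spatially smooth unit-variance texture: iid normals on a coarse grid
# (correlation length ~16 px), bilinearly upsampled. Mucosa colour varies at
# the scale of tissue patches, not pixels; pixel-scale noise would both turn
# the narrow contrast window into salt-and-pepper and drive the crack
# filter's tissue response below its printed threshold on crack-free mucosa.
smooth_field <- function(h, w, step = 16) {
  gh <- ceiling(h / step) + 1L
  gw <- ceiling(w / step) + 1L
  z <- matrix(rnorm(gh * gw), gh, gw)
  # bilinear interpolation of the coarse grid at pixel centres
  gr <- (seq_len(h) - 1) / step + 1
  gc <- (seq_len(w) - 1) / step + 1
  r0 <- pmin(floor(gr), gh - 1L); fr <- gr - r0
  c0 <- pmin(floor(gc), gw - 1L); fc <- gc - c0
  a <- z[cbind(rep(r0, w), rep(c0, each = h))]
  b <- z[cbind(rep(r0 + 1L, w), rep(c0, each = h))]
  d <- z[cbind(rep(r0, w), rep(c0 + 1L, each = h))]
  e <- z[cbind(rep(r0 + 1L, w), rep(c0 + 1L, each = h))]
  wr <- rep(fr, w); wc <- rep(fc, each = h)
  v <- (1 - wr) * (1 - wc) * a + wr * (1 - wc) * b +
    (1 - wr) * wc * d + wr * wc * e
  z <- matrix(v, h, w)
  s <- sqrt(mean((z - mean(z))^2))
  if (s < 1e-12) return(matrix(0, h, w))
  (z - mean(z)) / s
}

draw_arc_pixels <- function(h, w, center_r, center_c, radius) {
  a0 <- runif(1, 0, 2 * pi)
  span <- runif(1, 0.6 * pi, 1.4 * pi)
  t <- seq(a0, a0 + span, length.out = max(30L, ceiling(radius * span * 2)))
  r <- round(center_r + radius * sin(t))
  c <- round(center_c + radius * cos(t))
  # thickness 2: each sample also marks its right and lower neighbour
  r <- c(r, r + 1L, r)
  c <- c(c, c, c + 1L)
  keep <- r >= 1 & r <= h & c >= 1 & c <= w
  cbind(r[keep], c[keep])
}

# Cracks are depressions ~3 px wide with shaded edges, not hard 1-px steps:
# the core is fully darkened, a 1-px penumbra half-darkened.
draw_crack_pixels <- function(h, w, start_r, start_c) {
  len <- sample(15:45, 1)
  dir <- runif(1, 0, 2 * pi)
  r <- numeric(len); c <- numeric(len)
  pr <- start_r; pc <- start_c
  for (i in seq_len(len)) {
    r[i] <- pr; c[i] <- pc
    dir <- dir + rnorm(1, 0, 0.35)
    pr <- pr + sin(dir); pc <- pc + cos(dir)
  }
  r <- round(r); c <- round(c)
  lin_of <- function(dr, dc) {
    rr <- r + dr; cc <- c + dc
    keep <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    rr[keep] + (cc[keep] - 1) * h
  }
  core <- unique(unlist(lapply(-1:1, function(dr)
    lapply(-1:1, function(dc) lin_of(dr, dc)))))
  ring <- unique(unlist(lapply(-2:2, function(dr)
    lapply(-2:2, function(dc)
      if (max(abs(dr), abs(dc)) == 2L) lin_of(dr, dc)))))
  list(core = core, edge = setdiff(ring, core))
}

render_text_block <- function(h, w, string, top = 4L, left = 4L, scale = 2L) {
  idx <- NULL
  col <- left
  for (ch in strsplit(string, "")[[1]]) {
    glyph <- ce_font[[ch]]
    if (is.null(glyph)) next
    bits <- do.call(rbind, lapply(glyph, function(row)
      as.integer(strsplit(row, "")[[1]])))
    on <- which(bits == 1L, arr.ind = TRUE)
    for (k in seq_len(nrow(on))) {
      rr <- top + (on[k, 1] - 1L) * scale + seq_len(scale) - 1L
      cc <- col + (on[k, 2] - 1L) * scale + seq_len(scale) - 1L
      idx <- rbind(idx, as.matrix(expand.grid(rr, cc)))
    }
    col <- col + (3L + 1L) * scale
  }
  if (is.null(idx)) return(matrix(integer(), 0, 2))
  keep <- idx[, 1] >= 1 & idx[, 1] <= h & idx[, 2] >= 1 & idx[, 2] <= w
  idx[keep, , drop = FALSE]
}

#' Generate one synthetic capsule-endoscopy frame
#'
#' Deterministic given `seed`: black background, circular mucosa field of
#' class-conditioned colour with smooth Gaussian texture, `n_folds` bright
#' ridge arcs, `Poisson(crack_density)` dark crack polylines, and optionally
#' a white timestamp block near the top-left corner.
#'
#' @param p A [phenotype_params()] object.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An `H x W x 3` frame.
#' @export
generate_frame <- function(p, seed = NULL) {
  stopifnot(inherits(p, "phenotype_params"))
  render <- function() {
    h <- p$frame_size[1]; w <- p$frame_size[2]
    cr <- (h + 1) / 2; cc <- (w + 1) / 2
    radius <- p$field_radius_fraction * min(h, w) / 2
    dist <- sqrt(outer((seq_len(h) - cr)^2, (seq_len(w) - cc)^2, "+"))
    disk <- dist <= radius

    tex <- smooth_field(h, w)
    chan <- lapply(1:3, function(ch)
      p$base_rgb_mean[ch] + p$base_rgb_noise_std * tex)

    # folds: bright ridge arcs inside the field
    if (p$n_folds > 0) for (f in seq_len(p$n_folds)) {
      ocr <- cr + runif(1, -0.3, 0.3) * radius
      occ <- cc + runif(1, -0.3, 0.3) * radius
      px <- draw_arc_pixels(h, w, ocr, occ, runif(1, 0.35, 0.95) * radius)
      if (nrow(px) == 0) next
      lin <- px[, 1] + (px[, 2] - 1L) * h
      for (ch in 1:3) chan[[ch]][lin] <- chan[[ch]][lin] + p$fold_brightness
    }

    # cracks: dark polylines, Poisson count
    n_cracks <- rpois(1, p$crack_density)
    if (n_cracks > 0) for (cix in seq_len(n_cracks)) {
      repeat {
        sr <- runif(1, cr - radius, cr + radius)
        sc <- runif(1, cc - radius, cc + radius)
        if (sqrt((sr - cr)^2 + (sc - cc)^2) <= 0.85 * radius) break
      }
      px <- draw_crack_pixels(h, w, sr, sc)
      half <- (1 + p$crack_darkness) / 2
      for (ch in 1:3) {
        chan[[ch]][px$core] <- chan[[ch]][px$core] * p$crack_darkness
        chan[[ch]][px$edge] <- chan[[ch]][px$edge] * half
      }
    }

    frame <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      v <- pmin(pmax(chan[[ch]], 0.02), 1)   # keep the field strictly non-black
      v[!disk] <- 0
      frame[, , ch] <- v
    }

    if (p$overlay_text) {
      stamp <- sprintf("%02d:%02d", sample(0:23, 1), sample(0:59, 1))
      idx <- render_text_block(h, w, stamp)
      if (nrow(idx) > 0) {
        lin <- idx[, 1] + (idx[, 2] - 1L) * h
        npix <- h * w
        frame[c(lin, lin + npix, lin + 2L * npix)] <- 1
      }
    }
    frame
  }
  if (is.null(seed)) render() else withr::with_seed(seed, render())
}

#' Specification of one synthetic video
#'
#' @param phenotype A [phenotype_params()] object.
#' @param n_frames Number of frames (>= 2). Default 100, the nominal video
#'   length of the capsule recordings.
#' @param seed Integer seed for the whole video.
#' @return A `video_spec` list.
#' @export
video_spec <- function(phenotype, n_frames = 100, seed = 1) {
  stopifnot(inherits(phenotype, "phenotype_params"), n_frames >= 2)
  structure(list(phenotype = phenotype, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "video_spec")
}

frame_seed <- function(video_seed, i) {
  as.integer((as.double(video_seed) + i * 10007) %% 2147483629)
}

#' Generate a synthetic video
#'
#' `n_frames` frames sharing the phenotype, each rendered with a per-frame
#' derived seed so fold and crack placement jitters from frame to frame.
#' Bitwise reproducible from the spec.
#'
#' @param spec A [video_spec()].
#' @return List of frames.
#' @export
generate_video <- function(spec) {
  stopifnot(inherits(spec, "video_spec"))
  lapply(seq_len(spec$n_frames), function(i)
    generate_frame(spec$phenotype, seed = frame_seed(spec$seed, i)))
}

#' Generate a labeled synthetic dataset of videos
#'
#' Default class phenotypes; per-video derived seeds; reproducible.
#'
#' @param n_healthy,n_celiac Number of videos per class (>= 1).
#' @param seed Master seed.
#' @param n_frames Frames per video.
#' @param healthy,celiac Phenotype overrides per class.
#' @param materialize If `TRUE` (default) render all frames into `$videos`;
#'   if `FALSE` return only the specs (render on demand to bound memory).
#' @return List with `specs` (list of [video_spec()]), `labels`, `ids`, and
#'   (if materialized) `videos`.
#' @export
generate_dataset <- function(n_healthy, n_celiac, seed = 1, n_frames = 100,
                             healthy = phenotype_params("healthy"),
                             celiac = phenotype_params("celiac"),
                             materialize = TRUE) {
  stopifnot(n_healthy >= 1, n_celiac >= 1)
  labels <- c(rep("healthy", n_healthy), rep("celiac", n_celiac))
  ids <- c(sprintf("healthy_%03d", seq_len(n_healthy)),
           sprintf("celiac_%03d", seq_len(n_celiac)))
  vseeds <- vapply(seq_along(labels), function(i)
    as.integer((as.double(seed) + i * 97003) %% 2147483629), integer(1))
  specs <- lapply(seq_along(labels), function(i)
    video_spec(if (labels[i] == "healthy") healthy else celiac,
               n_frames = n_frames, seed = vseeds[i]))
  out <- list(specs = specs, labels = labels, ids = ids)
  if (materialize) out$videos <- lapply(specs, generate_video)
  out
}
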