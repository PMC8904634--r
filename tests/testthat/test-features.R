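test_that("spectral_stats computes intensity and channel moments", {
  expect_equal(unname(spectral_stats(solid_frame(4, 4))), rep(0, 5))

  red <- spectral_stats(solid_frame(4, 4, c(1, 0, 0)))
  expect_equal(unname(red[c("red_mean", "green_mean", "blue_mean")]),
               c(1, 0, 0))

  g <- cbind(matrix(0.2, 4, 2), matrix(0.4, 4, 2))
  ss <- spectral_stats(gray_frame(g))
  expect_equal(unname(ss["intensity_mean"]), 0.3)
  expect_equal(unname(ss["intensity_std"]), 0.1)   # population moments
})

test_that("frame_entropy hits the canonical histogram cases exactly", {
  expect_identical(frame_entropy(matrix(0.25, 8, 8)), 0)
  two <- cbind(matrix(0, 4, 4), matrix(1, 4, 4))
  expect_identical(frame_entropy(two), 1)
  uniform <- matrix((0:255) / 255, 16, 16)
  expect_identical(frame_entropy(uniform), 8)
})

test_that("frame_entropy is invariant under gray-level relabeling", {
  for (seed in 1:5) {
    lv <- withr::with_seed(seed, sample(0:255, 16, replace = FALSE))
    img <- matrix(rep(lv, each = 4) / 255, 8, 8)
    perm <- withr::with_seed(seed + 100, sample(0:255))
    relabeled <- matrix(perm[as.integer(round(img * 255)) + 1L] / 255, 8, 8)
    expect_equal(frame_entropy(relabeled), frame_entropy(img))
  }
})

test_that("mask_pixel_sum counts 1-pixels", {
  expect_identical(mask_pixel_sum(matrix(0L, 5, 5)), 0L)
  expect_identical(mask_pixel_sum(matrix(1L, 64, 64)), 4096L)
  m <- withr::with_seed(3, matrix(rbinom(100, 1, 0.4), 10, 10))
  n <- 0L
  for (i in 1:10) for (j in 1:10) if (m[i, j] == 1L) n <- n + 1L
  expect_identical(mask_pixel_sum(m), n)
  expect_error(mask_pixel_sum(matrix(0.5, 3, 3)), "0 and 1")
})

test_that("count_regions fills holes and splits by area", {
  expect_equal(count_regions(matrix(0L, 10, 10)),
               c(n_large = 0L, n_small = 0L))

  m <- matrix(0L, 80, 80)
  m[2:51, 2:31] <- 1L        # 1500-px blob
  m[60:64, 2:11] <- 1L       # 50-px blob
  m[60:64, 40:49] <- 1L      # 50-px blob
  expect_equal(count_regions(m), c(n_large = 1L, n_small = 2L))

  sq <- matrix(0L, 60, 60)
  sq[10:49, 10:49] <- 1L     # 1600 px
  sq[25:34, 25:34] <- 0L     # 100-px hole: filled before measuring
  expect_equal(fill_holes(sq)[25:34, 25:34], matrix(1L, 10, 10))
  expect_equal(count_regions(sq), c(n_large = 1L, n_small = 0L))
})

test_that("large-region count is non-increasing in the area threshold", {
  m <- withr::with_seed(5, matrix(rbinom(64 * 64, 1, 0.45), 64, 64))
  thresholds <- c(5, 20, 100, 500, 2000)
  nl <- vapply(thresholds,
               function(at) count_regions(m, area_threshold = at)[["n_large"]],
               integer(1))
  expect_true(all(diff(nl) <= 0))
})

test_that("frame_features composes the ten descriptors", {
  ff <- frame_features(solid_frame(16, 16, c(0.5, 0.5, 0.5)))
  expect_identical(names(ff), feature_names())
  expect_length(ff, 10)
  expect_equal(unname(ff["entropy"]), 0)
  expect_equal(unname(ff["sobel_sum"]), 0)
  expect_equal(unname(ff["n_large_regions"]), 0)
  expect_equal(unname(ff["n_small_regions"]), 0)
})

test_that("summarize_video computes mean/std/variation per feature", {
  one <- frame_features(disk_frame(32, 32))
  sv <- summarize_video(list(one, one, one))
  expect_length(sv, 30)
  expect_equal(unname(sv["red_mean_std"]), 0)
  expect_equal(unname(sv["entropy_variation"]), 0)

  # two-point moments on a hand-built feature matrix
  x <- matrix(rep(c(0.31, 0.33), each = 1), nrow = 2, ncol = 10)
  colnames(x) <- feature_names()
  sv2 <- summarize_video(x)
  expect_equal(unname(sv2["intensity_mean_mean"]), 0.32)
  expect_equal(unname(sv2["intensity_mean_std"]), 0.01)
  expect_equal(unname(sv2["intensity_mean_variation"]), 1e-4)

  expect_error(summarize_video(x[1, , drop = FALSE]), "at least 2")
})

test_that("variation equals std^2 and summaries ignore frame order", {
  x <- withr::with_seed(7, matrix(runif(50), 5, 10))
  colnames(x) <- feature_names()
  sv <- summarize_video(x)
  stds <- sv[grep("_std$", names(sv))]
  vars <- sv[grep("_variation$", names(sv))]
  expect_equal(unname(vars), unname(stds)^2)

  perm <- withr::with_seed(8, sample(5))
  expect_equal(summarize_video(x[perm, ]), sv)
})

test_that("augmentations satisfy their group identities", {
  fr <- disk_frame(32, 32, radius = 9, center = c(12, 20))
  expect_equal(augment_frame(augment_frame(fr, "mirror_h"), "mirror_h"), fr)
  expect_equal(augment_frame(augment_frame(fr, "mirror_v"), "mirror_v"), fr)

  r <- fr
  for (i in 1:4) r <- augment_frame(r, "rotate90")
  expect_equal(r, fr)
  expect_equal(augment_frame(augment_frame(fr, "rotate90"), "rotate180"),
               augment_frame(fr, "rotate270"))

  expect_equal(augment_frame(fr, "zoom", factor = 1), fr)
  expect_error(augment_frame(fr, "zoom", factor = 3), "factor")

  # non-square rotation transposes the geometry
  rect <- solid_frame(10, 16, c(0.2, 0.4, 0.6))
  expect_equal(dim(augment_frame(rect, "rotate90")), c(16L, 10L, 3L))
})

test_that("spectral means are invariant under mirrors and rotations", {
  fr <- withr::with_seed(12, {
    arr <- array(runif(24 * 24 * 3), dim = c(24, 24, 3))
    arr
  })
  base <- spectral_stats(fr)
  for (op in c("rotate90", "rotate180", "rotate270", "mirror_h", "mirror_v"))
    expect_equal(spectral_stats(augment_frame(fr, op)), base)
})
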