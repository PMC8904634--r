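# Independent oracles and fixture builders shared across the suite. The
# oracles are deliberately naive (exhaustive loops) and never call the code
# paths they check.

# Brute-force true 2-D convolution with mirror (no edge repeat) boundary.
oracle_convolve2d <- function(x, k) {
  h <- nrow(x); w <- ncol(x)
  refl <- function(i, n) {
    if (i < 1) 2 - i else if (i > n) 2 * n - i else i
  }
  out <- matrix(0, h, w)
  for (m in seq_len(h)) for (n in seq_len(w)) {
    s <- 0
    for (di in -1:1) for (dj in -1:1) {
      s <- s + k[di + 2, dj + 2] * x[refl(m - di, h), refl(n - dj, w)]
    }
    out[m, n] <- s
  }
  out
}

# Exhaustive distance-sort k-NN prediction (majority or inverse-distance).
# Ties have probability zero on the random instances it is used with.
oracle_knn_predict <- function(train_x, train_y, q, k, weighted = FALSE) {
  d <- apply(train_x, 1, function(p) sqrt(sum((p - q)^2)))
  nb <- order(d)[seq_len(k)]
  if (weighted) {
    if (d[nb[1]] < 1e-12) return(train_y[nb[1]])
    score <- tapply(1 / d[nb], train_y[nb], sum)
    names(score)[which.max(score)]
  } else {
    tab <- table(train_y[nb])
    names(tab)[which.max(tab)]
  }
}

# Bright disk on black, as an RGB frame.
disk_frame <- function(h = 64, w = 64, value = 0.8, radius = 20,
                       center = c((h + 1) / 2, (w + 1) / 2)) {
  d <- sqrt(outer((seq_len(h) - center[1])^2, (seq_len(w) - center[2])^2, "+"))
  g <- matrix(0, h, w)
  g[d <= radius] <- value
  gray_frame(g)
}

# Paint a solid rectangle into all channels of a frame.
paint_rect <- function(frame, rows, cols, value = 1) {
  for (ch in 1:3) frame[rows, cols, ch] <- value
  frame
}

# One-sided permutation test for a monotone trend of `values` in `levels`.
perm_trend_p <- function(levels, values, direction = c("increasing",
                                                       "decreasing"),
                         B = 999, seed = 1) {
  direction <- match.arg(direction)
  obs <- stats::cor(levels, values)
  perm <- withr::with_seed(seed,
    replicate(B, stats::cor(levels, sample(values))))
  if (direction == "decreasing") (1 + sum(perm <= obs)) / (B + 1)
  else (1 + sum(perm >= obs)) / (B + 1)
}

# Small well-separated two-class dataset for classifier tests.
toy_dataset <- function(n_per_class = 10, dim = 3, sep = 6, sd = 0.5,
                        seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * dim, 0, sd), n_per_class),
               matrix(rnorm(n_per_class * dim, sep, sd), n_per_class))
  })
  tab <- data.frame(video_id = sprintf("v%02d", seq_len(2 * n_per_class)),
                    label = rep(c("healthy", "celiac"), each = n_per_class))
  ds <- list(x = x,
             labels = tab$label,
             ids = tab$video_id)
  structure(ds, class = "ce_dataset")
}
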