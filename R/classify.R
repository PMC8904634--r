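# The classifier trio (3-NN, inverse-distance-weighted 3-NN, linear
# hinge-loss SVM), the stratified split, feature standardization, and the
# evaluation metrics.

#' Stratified train/test split
#'
#' Splits a dataset so each class contributes `train_fraction` of its members
#' (rounded) to the training set; seeded and reproducible.
#'
#' @param ds A `ce_dataset` (see [as_dataset()]).
#' @param train_fraction Fraction of each class assigned to training.
#'   Default 0.5.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return List with `ce_dataset` elements `train` and `test`.
#' @export
split_dataset <- function(ds, train_fraction = 0.5, seed = NULL) {
  stopifnot(inherits(ds, "ce_dataset"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must lie in (0, 1)", call. = FALSE)
  classes <- unique(ds$labels)
  counts <- table(ds$labels)
  if (any(counts < 2))
    stop("every class needs at least 2 members to stratify", call. = FALSE)
  pick <- function() {
    unlist(lapply(classes, function(cl) {
      idx <- which(ds$labels == cl)
      n_tr <- max(1L, min(length(idx) - 1L, round(train_fraction * length(idx))))
      sample(idx, n_tr)
    }))
  }
  tr <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  tr <- sort(tr)
  list(train = dataset_subset(ds, tr),
       test = dataset_subset(ds, setdiff(seq_len(nrow(ds$x)), tr)))
}

#' Fit column standardization on a dataset
#'
#' Z-scores every column with its (population) mean and standard deviation;
#' zero-variance columns map to 0. The returned scaler is fit on this
#' dataset (normally the training set) and can be applied to another with
#' [apply_standardization()].
#'
#' @param ds A `ce_dataset` with at least 2 rows.
#' @return List with the standardized `dataset` and the `scaler`
#'   (`center`, `scale`).
#' @export
standardize <- function(ds) {
  stopifnot(inherits(ds, "ce_dataset"))
  if (nrow(ds$x) < 2) stop("need at least 2 rows to standardize", call. = FALSE)
  center <- colMeans(ds$x)
  s <- sqrt(pmax(colMeans(ds$x^2) - center^2, 0))
  scaler <- structure(list(center = center, scale = s), class = "ce_scaler")
  list(dataset = apply_standardization(scaler, ds), scaler = scaler)
}

#' Apply a fitted standardization to a dataset
#'
#' @param scaler Scaler from [standardize()].
#' @param ds A `ce_dataset` with matching columns.
#' @return Standardized `ce_dataset`.
#' @export
apply_standardization <- function(scaler, ds) {
  stopifnot(inherits(scaler, "ce_scaler"), inherits(ds, "ce_dataset"))
  mult <- ifelse(scaler$scale > 0, 1 / scaler$scale, 0)
  xs <- sweep(sweep(ds$x, 2, scaler$center, "-"), 2, mult, "*")
  new_dataset(xs, ds$labels, ds$ids)
}

# ---- k-nearest neighbours ---------------------------------------------------

fit_knn <- function(ds, k, weighted) {
  stopifnot(inherits(ds, "ce_dataset"))
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
    stop("`k` must be a positive integer", call. = FALSE)
  if (k > nrow(ds$x))
    stop("`k` cannot exceed the number of training samples", call. = FALSE)
  if (length(unique(ds$labels)) < 2)
    stop("training data must contain both classes", call. = FALSE)
  structure(list(kind = if (weighted) "weighted_knn" else "fine_knn",
                 x = ds$x, labels = ds$labels, k = as.integer(k),
                 weighted = weighted),
            class = "ce_knn")
}

#' Fit a fine (majority-vote) k-NN classifier
#'
#' Prediction is the majority class among the `k` Euclidean-nearest training
#' neighbours; a majority tie is broken in favour of the class of the nearest
#' neighbour among the tied classes.
#'
#' @param ds Training `ce_dataset`.
#' @param k Number of neighbours. Default 3.
#' @return A `ce_knn` classifier.
#' @export
fit_fine_knn <- function(ds, k = 3) fit_knn(ds, k, weighted = FALSE)

#' Fit an inverse-distance-weighted k-NN classifier
#'
#' Among the `k` Euclidean-nearest neighbours each casts a vote of weight
#' `1/distance`; the class with the largest weight sum wins, so a couple of
#' very close neighbours can outvote a larger number of distant ones. A query
#' coinciding with a training point takes that point's label (infinite
#' weight).
#'
#' @inheritParams fit_fine_knn
#' @return A `ce_knn` classifier.
#' @export
fit_weighted_knn <- function(ds, k = 3) fit_knn(ds, k, weighted = TRUE)

#' @export
predict.ce_knn <- function(object, newdata, ...) {
  if (inherits(newdata, "ce_dataset")) newdata <- newdata$x
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  vapply(seq_len(nrow(newdata)), function(i) {
    q <- newdata[i, ]
    d <- sqrt(colSums((t(object$x) - q)^2))
    ord <- order(d)                       # stable: equidistant ties by row order
    nb <- ord[seq_len(object$k)]
    lb <- object$labels[nb]
    if (object$weighted) {
      if (d[nb[1]] < 1e-12) return(lb[1])
      w <- tapply(1 / d[nb], lb, sum)
      winners <- names(w)[w == max(w)]
    } else {
      tab <- table(lb)
      winners <- names(tab)[tab == max(tab)]
    }
    if (length(winners) == 1L) winners else lb[match(TRUE, lb %in% winners)]
  }, character(1))
}

# ---- linear SVM -------------------------------------------------------------

#' Fit a linear hinge-loss SVM
#'
#' Minimizes `||w||^2 / 2 + sum_i C_i * max(0, 1 - y_i (w.x_i + b))` by dual
#' coordinate descent (deterministic sequential sweeps), with the intercept
#' fitted through an appended constant feature. Class weights are balanced:
#' `C_i = C * n / (2 * n_class(i))`, i.e. inversely proportional to class
#' frequency. Iteration stops when the largest projected dual gradient falls
#' below `tol`.
#'
#' @param ds Training `ce_dataset` containing both classes.
#' @param C Regularization strength. Default 1.
#' @param tol Convergence tolerance on the projected gradient. Default 1e-3.
#' @param max_epochs Maximum coordinate-descent sweeps. Default 1000.
#' @param positive_class Label mapped to +1 (default `"celiac"`; falls back
#'   to the first sorted label if absent).
#' @return A `ce_svm` classifier with weights `w` and intercept `b`.
#' @export
fit_linear_svm <- function(ds, C = 1, tol = 1e-3, max_epochs = 1000,
                           positive_class = "celiac") {
  stopifnot(inherits(ds, "ce_dataset"))
  classes <- sort(unique(ds$labels))
  if (length(classes) < 2)
    stop("training data must contain both classes", call. = FALSE)
  if (!positive_class %in% classes) positive_class <- classes[1]
  negative_class <- setdiff(classes, positive_class)[1]
  y <- ifelse(ds$labels == positive_class, 1, -1)
  n <- length(y)
  xa <- cbind(ds$x, 1)                       # regularized intercept feature
  ci <- C * n / (2 * table(ds$labels)[ds$labels])
  ci <- as.numeric(ci)
  qii <- rowSums(xa^2)
  alpha <- numeric(n)
  w <- numeric(ncol(xa))
  converged <- FALSE
  epochs <- 0L
  for (epoch in seq_len(max_epochs)) {
    epochs <- epoch
    max_pg <- 0
    for (i in seq_len(n)) {
      if (qii[i] == 0) next
      g <- y[i] * sum(w * xa[i, ]) - 1
      pg <- if (alpha[i] <= 0) min(g, 0) else if (alpha[i] >= ci[i]) max(g, 0) else g
      if (abs(pg) > max_pg) max_pg <- abs(pg)
      if (abs(pg) > 1e-14) {
        a_new <- min(max(alpha[i] - g / qii[i], 0), ci[i])
        if (a_new != alpha[i]) {
          w <- w + (a_new - alpha[i]) * y[i] * xa[i, ]
          alpha[i] <- a_new
        }
      }
    }
    if (max_pg < tol) { converged <- TRUE; break }
  }
  p <- ncol(ds$x)
  structure(list(kind = "linear_svm", w = w[seq_len(p)], b = w[p + 1L],
                 positive_class = positive_class,
                 negative_class = negative_class,
                 C = C, tol = tol, epochs = epochs, converged = converged),
            class = "ce_svm")
}

#' @export
predict.ce_svm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "ce_dataset")) newdata <- newdata$x
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  scores <- drop(newdata %*% object$w) + object$b
  if (type == "decision") return(scores)
  ifelse(scores >= 0, object$positive_class, object$negative_class)
}

# ---- evaluation -------------------------------------------------------------

#' Evaluate a classifier on a test set
#'
#' Confusion counts with the celiac class as positive, plus accuracy (in
#' percent), precision `tp/(tp+fp)`, sensibility (recall) `tp/(tp+fn)`, and
#' the F1 score `tp / (tp + (fp + fn)/2)`.
#'
#' @param clf A fitted `ce_knn` or `ce_svm` classifier.
#' @param test Test `ce_dataset` (non-empty).
#' @param positive_class Positive label. Default `"celiac"`.
#' @return An `evaluation_report`: list with `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`, `precision`, `sensibility`, `f1`, `n`, `kind`, and a
#'   `precision_undefined` flag (`TRUE` when `tp + fp = 0`, in which case
#'   precision is reported as 0 with a warning).
#' @export
evaluate <- function(clf, test, positive_class = "celiac") {
  stopifnot(inherits(test, "ce_dataset"))
  if (nrow(test$x) == 0) stop("test set is empty", call. = FALSE)
  pred <- predict(clf, test$x)
  truth <- test$labels
  tp <- sum(pred == positive_class & truth == positive_class)
  fp <- sum(pred == positive_class & truth != positive_class)
  tn <- sum(pred != positive_class & truth != positive_class)
  fn <- sum(pred != positive_class & truth == positive_class)
  n <- length(truth)
  precision_undefined <- (tp + fp) == 0
  if (precision_undefined)
    warning("no positive predictions: precision undefined, reported as 0",
            call. = FALSE)
  structure(list(
    kind = clf$kind, n = n, positive_class = positive_class,
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = 100 * (tp + tn) / n,
    precision = if (precision_undefined) 0 else tp / (tp + fp),
    sensibility = if ((tp + fn) == 0) 0 else tp / (tp + fn),
    f1 = f1_score(tp, fp, fn),
    precision_undefined = precision_undefined
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation (%s), n = %d, positive = %s\n",
              x$kind, x$n, x$positive_class))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(m)
  cat(sprintf("accuracy    %.1f %%\nprecision   %.4f\nsensibility %.4f\nF1          %.4f\n",
              x$accuracy, x$precision, x$sensibility, x$f1))
  invisible(x)
}

#' F1 score from confusion counts
#'
#' `F1 = tp / (tp + (fp + fn) / 2)`; defined as 0 when the denominator is 0.
#'
#' @param tp,fp,fn True-positive, false-positive, false-negative counts.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(tp, fp, fn) {
  den <- tp + 0.5 * (fp + fn)
  if (den == 0) return(0)
  tp / den
}

#' F1 score from precision and sensibility
#'
#' The harmonic mean `2PR/(P+R)`, algebraically equal to the count form
#' whenever both are defined. `truncate = TRUE` truncates (not rounds) to two
#' decimals, the convention needed to reproduce published two-decimal tables.
#'
#' @param precision,sensibility Precision and recall in `[0, 1]`.
#' @param truncate Truncate the result to two decimals.
#' @return F1 in `[0, 1]`.
#' @export
f1_from_pr <- function(precision, sensibility, truncate = FALSE) {
  if (precision + sensibility == 0) return(0)
  f <- 2 * precision * sensibility / (precision + sensibility)
  if (truncate) floor(f * 100) / 100 else f
}

#' Accuracy from test counts, in percent
#'
#' `100 * (total - errors) / total`, reported to one decimal.
#'
#' @param total Number of tests (> 0).
#' @param errors Number of misclassified tests.
#' @return Percentage rounded to one decimal.
#' @export
accuracy_from_counts <- function(total, errors) {
  if (!is.numeric(total) || total <= 0)
    stop("`total` must be positive", call. = FALSE)
  if (errors < 0 || errors > total)
    stop("`errors` must lie in [0, total]", call. = FALSE)
  round(100 * (total - errors) / total, 1)
}
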