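# The per-video feature table: one row per video with its id, class label,
# and the 30 summary columns (10 features x mean/std/variation), persisted
# as a plain CSV.

summary_column_names <- function() {
  as.vector(t(outer(ce_feature_names, ce_stat_names, paste, sep = "_")))
}

#' Assemble a feature table from per-video summaries
#'
#' @param summaries List of [summarize_video()] vectors (length-30 each).
#' @param labels Character vector of class labels (`"healthy"`/`"celiac"`).
#' @param ids Character vector of unique video identifiers.
#' @return `data.frame` with columns `video_id`, `label`, then the 30
#'   summary columns in canonical order.
#' @export
feature_table <- function(summaries, labels, ids) {
  if (length(summaries) != length(labels) || length(labels) != length(ids))
    stop("summaries, labels and ids must have equal length", call. = FALSE)
  if (anyDuplicated(ids))
    stop("video ids must be unique", call. = FALSE)
  cols <- summary_column_names()
  x <- do.call(rbind, lapply(summaries, function(s) s[cols]))
  out <- data.frame(video_id = as.character(ids), label = as.character(labels),
                    x, check.names = FALSE, row.names = NULL)
  out
}

#' Write a feature table to CSV
#'
#' Comma-separated, UTF-8, header row, `.` decimal separator.
#'
#' @param table Feature table data frame.
#' @param path Output CSV path.
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path written by [write_feature_table()].
#' @return Feature table data frame.
#' @export
read_feature_table <- function(path) {
  out <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                  stringsAsFactors = FALSE)
  need <- c("video_id", "label", summary_column_names())
  if (!all(need %in% names(out)))
    stop("not a feature table CSV: columns missing", call. = FALSE)
  out[, need]
}

#' Convert a feature table to a classification dataset
#'
#' @param table Feature table data frame.
#' @return A `ce_dataset`: list with numeric matrix `x` (one row per video),
#'   character `labels`, and character `ids`.
#' @export
as_dataset <- function(table) {
  cols <- summary_column_names()
  x <- as.matrix(table[, cols])
  storage.mode(x) <- "double"
  rownames(x) <- table$video_id
  new_dataset(x, as.character(table$label), as.character(table$video_id))
}

new_dataset <- function(x, labels, ids) {
  if (nrow(x) != length(labels) || length(labels) != length(ids))
    stop("dataset parts must have equal length", call. = FALSE)
  if (anyDuplicated(ids)) stop("dataset ids must be unique", call. = FALSE)
  structure(list(x = x, labels = labels, ids = ids), class = "ce_dataset")
}

dataset_subset <- function(ds, idx) {
  new_dataset(ds$x[idx, , drop = FALSE], ds$labels[idx], ds$ids[idx])
}

#' @export
print.ce_dataset <- function(x, ...) {
  cat(sprintf("<ce_dataset> %d videos x %d features; classes: %s\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}
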