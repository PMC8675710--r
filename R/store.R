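#' Save and load feature stores
#'
#' Single-file RDS store for `eeg_features` objects (tensor, labels,
#' identifiers and extraction attributes travel together); the companion
#' CSV exporters write tabular results for downstream tooling.
#'
#' @param features An `eeg_features` object.
#' @param path File path.
#' @return `load_features()` returns the restored `eeg_features`.
#' @export
save_features <- function(features, path) {
  stopifnot(inherits(features, "eeg_features"))
  saveRDS(features, path)
  invisible(path)
}

#' @rdname save_features
#' @export
load_features <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "eeg_features"))
  x
}

#' Export a metrics report as CSV
#'
#' Writes `<path>` with accuracy and sample count and
#' `<path base>_confusion.csv` with the confusion matrix.
#'
#' @param metrics A `metrics_report`.
#' @param path Output CSV path.
#' @return Invisibly, the paths written.
#' @export
export_metrics_csv <- function(metrics, path) {
  stopifnot(inherits(metrics, "metrics_report"))
  utils::write.csv(
    data.frame(accuracy = metrics$accuracy, n = metrics$n),
    path, row.names = FALSE
  )
  cpath <- sub("\\.csv$", "_confusion.csv", path)
  utils::write.csv(as.data.frame.matrix(metrics$confusion), cpath)
  invisible(c(path, cpath))
}

#' Export a region-contribution table as CSV
#'
#' @param contributions Data.frame from [region_contribution_map()].
#' @param path Output CSV path.
#' @return Invisibly, the path written.
#' @export
export_contributions_csv <- function(contributions, path) {
  utils::write.csv(contributions, path, row.names = FALSE)
  invisible(path)
}
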