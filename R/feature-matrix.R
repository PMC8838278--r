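#' Labeled feature matrix
#'
#' The currency of the selection, fusion and classification stages: an
#' n_samples x n_features numeric matrix plus per-sample class labels and a
#' free-text provenance tag.
#'
#' @param values Numeric matrix, one row per sample; all values finite.
#' @param labels Optional per-sample class labels (factor or coercible).
#' @param source Free-text provenance tag.
#' @return Object of class `feature_matrix`: list with `values`, `labels`,
#'   `source`.
#' @export
feature_matrix <- function(values, labels = NULL, source = "unknown") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 1L) stop("need at least one feature")
  if (any(!is.finite(values))) stop("non-finite feature values")
  if (!is.null(labels)) {
    if (length(labels) != nrow(values))
      stop("labels length must match the number of rows")
    labels <- factor(labels)
  }
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("f%04d", seq_len(ncol(values)))
  structure(list(values = values, labels = labels, source = source),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d features (%s)\n",
              nrow(x$values), ncol(x$values), x$source))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

## internal: subset rows / columns, keeping labels aligned
fm_subset <- function(fm, rows = NULL, cols = NULL) {
  v <- fm$values
  if (!is.null(rows)) v <- v[rows, , drop = FALSE]
  if (!is.null(cols)) v <- v[, cols, drop = FALSE]
  lab <- fm$labels
  if (!is.null(lab) && !is.null(rows)) lab <- lab[rows]
  feature_matrix(v, lab, fm$source)
}

#' Read a feature matrix from CSV/TSV
#'
#' Expects a header row and a `label` column; every other column must be
#' numeric. The delimiter is inferred from the file extension (`.tsv` means
#' tab, otherwise comma).
#'
#' @param path File path.
#' @param label_column Name of the label column (`NULL` for unlabeled data).
#' @return A [feature_matrix()].
#' @export
read_features <- function(path, label_column = "label") {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  labels <- NULL
  if (!is.null(label_column) && label_column %in% names(df)) {
    labels <- df[[label_column]]
    df[[label_column]] <- NULL
  }
  feature_matrix(as.matrix(df), labels, source = path)
}

#' Write a feature matrix to CSV/TSV
#'
#' @param fm A [feature_matrix()].
#' @param path Output path (`.tsv` writes tab-separated, otherwise comma).
#' @export
write_features <- function(fm, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(fm$values)
  if (!is.null(fm$labels)) df$label <- as.character(fm$labels)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an image from PNG
#'
#' Returns pixels on the 0-255 scale as a matrix (grayscale) or H x W x 3
#' array; a PNG alpha channel, if present, is dropped.
#'
#' @param path PNG file path.
#' @return Numeric matrix or array on the 0-255 scale.
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L && dim(a)[3] >= 3L) a <- a[, , 1:3, drop = FALSE]
  if (length(dim(a)) == 3L && dim(a)[3] == 1L) a <- a[, , 1L]
  a * 255
}

#' Write an image to PNG
#'
#' @param image Matrix or H x W x C array on the 0-255 scale.
#' @param path Output path.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}
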