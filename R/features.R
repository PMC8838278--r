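#' Valid-mode 2-D convolution (cross-correlation form)
#'
#' `z[i, j] = sum_a sum_b kernel[a, b] * image[i + a - 1, j + b - 1]`, no
#' padding, so an H x W image convolved with an n x m kernel yields
#' (H - n + 1) x (W - m + 1).
#'
#' @param image Numeric matrix.
#' @param kernel Numeric matrix no larger than `image` in either dimension.
#' @return Numeric matrix of the valid-mode output size.
#' @export
conv2d_valid <- function(image, kernel) {
  stopifnot(is.matrix(image), is.matrix(kernel))
  kh <- nrow(kernel); kw <- ncol(kernel)
  if (kh > nrow(image) || kw > ncol(image)) stop("kernel larger than image")
  oh <- nrow(image) - kh + 1L
  ow <- ncol(image) - kw + 1L
  out <- matrix(0, oh, ow)
  for (a in seq_len(kh)) {
    for (b in seq_len(kw)) {
      out <- out + kernel[a, b] * image[a:(a + oh - 1L), b:(b + ow - 1L)]
    }
  }
  out
}

#' Rectified linear activation
#'
#' @param values Numeric vector, matrix or array.
#' @return Elementwise `max(0, values)`, preserving shape.
#' @export
relu <- function(values) {
  if (any(!is.finite(values))) stop("non-finite values")
  pmax(values, 0)
}

#' 2-D pooling
#'
#' Slides a G x G window with stride Z over a matrix and reduces each window
#' by max, average or min. Output dimensions follow `(W1 - G)/Z + 1`; the
#' stride must divide `(W1 - G)` exactly in both dimensions.
#'
#' @param values Numeric matrix.
#' @param window Window size G (positive integer, no larger than either
#'   input dimension).
#' @param stride Stride Z (positive integer).
#' @param mode One of `"max"`, `"average"`, `"min"`.
#' @return Pooled matrix of size `((H1 - G)/Z + 1) x ((W1 - G)/Z + 1)`.
#' @export
pool2d <- function(values, window, stride = window,
                   mode = c("max", "average", "min")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(values), window >= 1, stride >= 1)
  h1 <- nrow(values); w1 <- ncol(values)
  if (window > h1 || window > w1) stop("pooling window larger than input")
  if ((h1 - window) %% stride != 0 || (w1 - window) %% stride != 0)
    stop("stride must divide (input size - window) exactly")
  h2 <- (h1 - window) / stride + 1L
  w2 <- (w1 - window) / stride + 1L
  f <- switch(mode, max = max, average = mean, min = min)
  out <- matrix(0, h2, w2)
  for (i in seq_len(h2)) {
    for (j in seq_len(w2)) {
      ri <- (i - 1L) * stride + 1L
      rj <- (j - 1L) * stride + 1L
      out[i, j] <- f(values[ri:(ri + window - 1L), rj:(rj + window - 1L)])
    }
  }
  out
}

#' Numerically stable softmax
#'
#' @param q Numeric vector (length >= 1, finite).
#' @return Probability vector: positive components summing to 1.
#' @export
softmax <- function(q) {
  if (length(q) == 0L) stop("empty vector")
  if (any(!is.finite(q))) stop("non-finite values")
  e <- exp(q - max(q))
  e / sum(e)
}

#' Backbone specification for feature extraction
#'
#' Describes how images are turned into feature vectors. The `"toy"` kind is
#' a deterministic backbone built from the generic convolution / ReLU /
#' pooling operators: each channel is smoothed with a normalized box kernel,
#' rectified, average-pooled, then partitioned into a `grid x grid` patch
#' grid, and per-patch mean, standard deviation and absolute mean deviation
#' are concatenated. The `"external"` kind is an adapter contract: any
#' function mapping a list of images to an n x p matrix (for real CNN
#' backbones, features taken from the global average pool layer); the
#' returned width is validated, not assumed.
#'
#' @param kind `"toy"` or `"external"`.
#' @param grid Patch grid size g for the toy backbone (feature width is
#'   `g^2 * 3 stats * channels`).
#' @param pool_mode Pooling reduction for the toy backbone.
#' @param extractor For `"external"`: `function(images) -> matrix`.
#' @param layer Free-text name of the extraction layer (metadata; for
#'   external CNN backbones conventionally the global average pool).
#' @param expected_width Optional integer; if given, the adapter's returned
#'   width is checked against it.
#' @return An object of class `backbone_spec`.
#' @export
backbone_spec <- function(kind = c("toy", "external"), grid = 4L,
                          pool_mode = "average", extractor = NULL,
                          layer = if (kind[1] == "toy") "toy" else "avg_pool",
                          expected_width = NULL) {
  kind <- match.arg(kind)
  if (kind == "external" && !is.function(extractor))
    stop("external backbone requires an extractor function")
  structure(list(kind = kind, grid = as.integer(grid), pool_mode = pool_mode,
                 extractor = extractor, layer = layer,
                 expected_width = expected_width),
            class = "backbone_spec")
}

## internal: toy-backbone feature vector for one image
toy_features_one <- function(image, grid, pool_mode) {
  arr <- as_image_array(image)
  box <- matrix(1 / 9, 3, 3)
  feats <- numeric(0)
  for (ch in seq_len(dim(arr)[3])) {
    x <- conv2d_valid(arr[, , ch], box)
    x <- relu(x)
    # crop to the largest window the stride divides exactly, then pool
    h <- nrow(x) - ((nrow(x) - 2L) %% 2L)
    w <- ncol(x) - ((ncol(x) - 2L) %% 2L)
    x <- pool2d(x[seq_len(h), seq_len(w), drop = FALSE], 2L, 2L, pool_mode)
    if (nrow(x) < grid || ncol(x) < grid)
      stop("image too small for the requested patch grid")
    rb <- split(seq_len(nrow(x)), cut(seq_len(nrow(x)), grid, labels = FALSE))
    cb <- split(seq_len(ncol(x)), cut(seq_len(ncol(x)), grid, labels = FALSE))
    for (i in seq_len(grid)) {
      for (j in seq_len(grid)) {
        p <- as.vector(x[rb[[i]], cb[[j]]])
        sdev <- if (length(p) > 1L) stats::sd(p) else 0
        feats <- c(feats, mean(p), sdev, compute_amd(p, mean(p)))
      }
    }
  }
  feats
}

#' Extract a feature matrix from images
#'
#' One row per image. The toy backbone is fully deterministic (same image,
#' same vector); an external backbone delegates to its adapter function and
#' validates that it returns one row per image with a consistent width.
#'
#' @param images List of images (matrices or H x W x C arrays).
#' @param labels Class labels, one per image (optional but required by the
#'   supervised downstream stages).
#' @param backbone A [backbone_spec()].
#' @return A [feature_matrix()].
#' @export
extract_features <- function(images, labels = NULL,
                             backbone = backbone_spec("toy")) {
  if (length(images) == 0L) stop("empty image list")
  stopifnot(inherits(backbone, "backbone_spec"))
  if (backbone$kind == "toy") {
    rows <- lapply(images, toy_features_one, grid = backbone$grid,
                   pool_mode = backbone$pool_mode)
    widths <- lengths(rows)
    if (length(unique(widths)) != 1L)
      stop("inconsistent feature widths across images")
    values <- do.call(rbind, rows)
    src <- sprintf("toy backbone (grid %d)", backbone$grid)
  } else {
    values <- backbone$extractor(images)
    if (!is.matrix(values) || nrow(values) != length(images))
      stop("external backbone must return one feature row per image")
    if (!is.null(backbone$expected_width) &&
        ncol(values) != backbone$expected_width)
      stop(sprintf("external backbone returned width %d, expected %d",
                   ncol(values), backbone$expected_width))
    src <- sprintf("external backbone (layer %s)", backbone$layer)
  }
  if (any(!is.finite(values))) stop("non-finite feature values")
  colnames(values) <- sprintf("f%04d", seq_len(ncol(values)))
  feature_matrix(values, labels, source = src)
}
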