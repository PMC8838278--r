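#' Absolute mean deviation of pixel values
#'
#' Mean absolute deviation of a set of pixel intensities from a supplied
#' reference mean. This statistic drives both the hybrid contrast stretch
#' (where the reference is the pooled dataset mean) and the refinement of the
#' whale optimizer's best solution (where the reference is the score mean).
#'
#' @param pixels Numeric vector of pixel values (at least one, all finite).
#' @param reference_mean Finite scalar reference intensity.
#' @return Non-negative scalar, `mean(abs(pixels - reference_mean))`.
#' @examples
#' compute_amd(c(0, 2, 4, 6), 3)  # 2
#' @export
compute_amd <- function(pixels, reference_mean) {
  if (length(pixels) == 0L) stop("empty image")
  stopifnot(is.numeric(pixels), length(reference_mean) == 1L,
            is.finite(reference_mean))
  if (any(!is.finite(pixels))) stop("non-finite pixel values")
  mean(abs(pixels - reference_mean))
}

#' Sample skewness of pixel values
#'
#' Third standardized moment with the sample (n - 1) convention:
#' `sum((x - mean(x))^3) / ((n - 1) * sd(x)^3)`. A constant input (zero
#' standard deviation) is defined to have skewness 0 so downstream formulas
#' never divide by zero.
#'
#' @param pixels Numeric vector of pixel values (at least one, all finite).
#' @return Scalar skewness; 0 for constant or single-pixel input.
#' @examples
#' compute_skewness(c(0, 0, 0, 4))  # 1
#' @export
compute_skewness <- function(pixels) {
  if (length(pixels) == 0L) stop("empty image")
  if (any(!is.finite(pixels))) stop("non-finite pixel values")
  n <- length(pixels)
  if (n < 2L) return(0)
  s <- stats::sd(pixels)
  if (s == 0) return(0)
  d <- pixels - mean(pixels)
  sum(d^3) / ((n - 1) * s^3)
}

## internal: coerce to H x W x C array, remember if input was a matrix
as_image_array <- function(image) {
  if (is.matrix(image)) {
    array(image, dim = c(dim(image), 1L))
  } else if (is.array(image) && length(dim(image)) == 3L) {
    if (!dim(image)[3] %in% c(1L, 3L)) stop("channels must be 1 or 3")
    image
  } else {
    stop("image must be a matrix or a height x width x channels array")
  }
}

#' Hybrid contrast enhancement of a single image
#'
#' Local contrast stretch combining the absolute mean deviation (AMD) of the
#' image against a reference mean with the image's own skewness. Per channel,
#' with `MD = compute_amd(x, reference_mean)` and `SK = compute_skewness(x)`,
#' the transform is `I1 = |MD + X|` elementwise followed by `IF = |I1 - SK|`,
#' and the result is clipped to the 8-bit display range [0, 255].
#'
#' @param image Numeric matrix (grayscale) or height x width x channels array
#'   with 1 or 3 channels, values on the 0-255 scale.
#' @param reference_mean Numeric scalar, or one value per channel. For
#'   dataset runs this is the pooled dataset mean (see [enhance_dataset()]);
#'   for single-image use the image's own mean is a sensible fallback.
#' @return Enhanced image of the same shape, values in [0, 255].
#' @seealso [enhance_dataset()] for the pooled-reference dataset workflow.
#' @examples
#' x <- matrix(c(0, 100, 100, 200), 2, 2)
#' enhance_image(x, 100)
#' @export
enhance_image <- function(image, reference_mean) {
  arr <- as_image_array(image)
  nc <- dim(arr)[3]
  if (!length(reference_mean) %in% c(1L, nc))
    stop("reference_mean must have one value, or one per channel")
  reference_mean <- rep_len(reference_mean, nc)
  out <- arr
  for (ch in seq_len(nc)) {
    x <- arr[, , ch]
    md <- compute_amd(as.vector(x), reference_mean[ch])
    sk <- compute_skewness(as.vector(x))
    i1 <- abs(md + x)
    out[, , ch] <- pmin(pmax(abs(i1 - sk), 0), 255)
  }
  if (is.matrix(image)) out[, , 1L] else out
}

#' Per-channel enhancement statistics for an image
#'
#' @param image Matrix or array as in [enhance_image()].
#' @param reference_mean Reference mean(s) used for the AMD.
#' @return Data frame with one row per channel: `channel`, `dataset_mean`
#'   (the reference), `image_mean`, `image_sd`, `amd`, `skewness`.
#' @export
enhancement_stats <- function(image, reference_mean) {
  arr <- as_image_array(image)
  nc <- dim(arr)[3]
  reference_mean <- rep_len(reference_mean, nc)
  do.call(rbind, lapply(seq_len(nc), function(ch) {
    x <- as.vector(arr[, , ch])
    data.frame(channel = ch,
               dataset_mean = reference_mean[ch],
               image_mean = mean(x),
               image_sd = stats::sd(x),
               amd = compute_amd(x, reference_mean[ch]),
               skewness = compute_skewness(x))
  }))
}

#' Enhance a whole dataset against its pooled mean
#'
#' Computes the per-channel mean pooled over all pixels of all images (the
#' dataset reference intensity) and applies [enhance_image()] to every image
#' with that reference. This is the intended mode of the contrast stretch:
#' the whole dataset is transformed once before any model training.
#'
#' @param images List of images (all with the same channel count).
#' @param per_image_mean If `TRUE`, each image is enhanced against its own
#'   mean instead of the pooled dataset mean.
#' @return List with `images` (enhanced), `reference_mean` (per channel) and
#'   `stats` (row-bound [enhancement_stats()] with an `image` index column).
#' @export
enhance_dataset <- function(images, per_image_mean = FALSE) {
  if (length(images) == 0L) stop("empty image list")
  arrs <- lapply(images, as_image_array)
  ncs <- vapply(arrs, function(a) dim(a)[3], integer(1))
  if (length(unique(ncs)) != 1L) stop("mixed channel counts")
  nc <- ncs[1]
  # pooled per-channel mean over every pixel of every image
  sums <- rep(0, nc); count <- 0
  for (a in arrs) {
    sums <- sums + vapply(seq_len(nc), function(ch) sum(a[, , ch]), numeric(1))
    count <- count + prod(dim(a)[1:2])
  }
  ref <- sums / count
  enh <- vector("list", length(images))
  stats_list <- vector("list", length(images))
  for (i in seq_along(images)) {
    r <- if (per_image_mean) {
      vapply(seq_len(nc), function(ch) mean(arrs[[i]][, , ch]), numeric(1))
    } else ref
    enh[[i]] <- enhance_image(images[[i]], r)
    st <- enhancement_stats(images[[i]], r)
    st$image <- i
    stats_list[[i]] <- st
  }
  list(images = enh, reference_mean = ref, stats = do.call(rbind, stats_list))
}
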