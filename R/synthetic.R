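#' Specification for a synthetic labeled feature matrix
#'
#' Describes a class-conditional Gaussian feature matrix with a known split
#' into informative, redundant and noise columns — the statistical structure
#' the selectors assume: a minority of class-separating columns hidden among
#' correlated and pure-noise columns. Seven balanced classes by default,
#' mirroring the seven-lesion-class setting the pipeline targets.
#'
#' @param n_samples Number of samples (>= 2 per class).
#' @param n_classes Number of classes (default 7).
#' @param n_informative Columns whose class means differ (>= 1).
#' @param n_redundant Columns that are random linear combinations of the
#'   informative ones plus N(0, 0.01) noise.
#' @param n_noise Standard-normal columns carrying no class signal.
#' @param class_separation Distance between class means in the informative
#'   dimensions, in units of the within-class standard deviation (1).
#' @param imbalance Dirichlet-style skew: 0 = balanced (default); larger
#'   values make class sizes proportional to `(1 + imbalance)^(-class index)`.
#' @param seed Integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 200L, n_classes = 7L,
                           n_informative = 8L, n_redundant = 0L,
                           n_noise = 52L, class_separation = 3,
                           imbalance = 0, seed = 0L) {
  stopifnot(n_informative >= 1, n_redundant >= 0, n_noise >= 0,
            n_classes >= 2, n_samples >= 2 * n_classes,
            class_separation >= 0, imbalance >= 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_classes = as.integer(n_classes),
                 n_informative = as.integer(n_informative),
                 n_redundant = as.integer(n_redundant),
                 n_noise = as.integer(n_noise),
                 class_separation = class_separation,
                 imbalance = imbalance, seed = as.integer(seed)),
            class = "synthetic_spec")
}

## internal: k class-mean vectors in p dimensions with pairwise distance sep
class_means <- function(k, p, sep, rng) {
  if (p >= k) {
    # scaled coordinate vectors: ||sep/sqrt(2) (e_i - e_j)|| = sep exactly,
    # then a random rotation so every coordinate carries class signal
    m <- matrix(0, k, p)
    m[cbind(seq_len(k), seq_len(k))] <- sep / sqrt(2)
    q <- qr.Q(qr(matrix(rng$rnorm(p * p), p, p)))
    m %*% q
  } else {
    # random directions rescaled so the mean pairwise distance equals sep
    m <- matrix(rng$rnorm(k * p), k, p)
    m <- sweep(m, 2, colMeans(m))
    dd <- as.matrix(stats::dist(m))
    avg <- mean(dd[upper.tri(dd)])
    if (avg > 0) m <- m * sep / avg
    m
  }
}

#' Generate a synthetic labeled feature matrix with known ground truth
#'
#' Informative columns are class-conditional Gaussians with unit standard
#' deviation and class means `class_separation` apart; redundant columns are
#' random linear combinations of the informative block plus N(0, 0.01)
#' noise; noise columns are standard normal. Classes are balanced (up to
#' rounding) unless `imbalance > 0`. Columns are informative first, then
#' redundant, then noise; the ground-truth index sets are returned so
#' selector recall can be measured exactly. Bit-reproducible per seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A [feature_matrix()] with attribute `ground_truth`: list of
#'   `informative`, `redundant`, `noise` column index vectors.
#' @export
make_features <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rng <- local_rng(spec$seed)
  k <- spec$n_classes
  sizes <- if (spec$imbalance == 0) {
    base <- spec$n_samples %/% k
    s <- rep(base, k)
    extra <- spec$n_samples - sum(s)
    if (extra > 0) s[seq_len(extra)] <- s[seq_len(extra)] + 1L
    s
  } else {
    w <- (1 + spec$imbalance)^(-(seq_len(k) - 1))
    s <- pmax(2L, round(spec$n_samples * w / sum(w)))
    s[1] <- s[1] + spec$n_samples - sum(s)
    if (any(s < 2L)) stop("infeasible counts under this imbalance")
    s
  }
  labels <- factor(rep(sprintf("class%d", seq_len(k)), times = sizes))
  n <- length(labels)
  p_inf <- spec$n_informative
  mu <- class_means(k, p_inf, spec$class_separation, rng)
  inf <- matrix(rng$rnorm(n * p_inf), n, p_inf) +
    mu[as.integer(labels), , drop = FALSE]
  blocks <- list(inf)
  if (spec$n_redundant > 0) {
    w <- matrix(rng$rnorm(p_inf * spec$n_redundant), p_inf)
    blocks <- c(blocks, list(inf %*% w +
      matrix(rng$rnorm(n * spec$n_redundant, sd = 0.1), n)))
  }
  if (spec$n_noise > 0)
    blocks <- c(blocks, list(matrix(rng$rnorm(n * spec$n_noise), n)))
  values <- do.call(cbind, blocks)
  perm <- rng$sample_vec(seq_len(n))   # shuffle sample order
  fm <- feature_matrix(values[perm, , drop = FALSE], labels[perm],
                       source = sprintf("synthetic (seed %d)", spec$seed))
  attr(fm, "ground_truth") <- list(
    informative = seq_len(p_inf),
    redundant = if (spec$n_redundant > 0)
      p_inf + seq_len(spec$n_redundant) else integer(0),
    noise = if (spec$n_noise > 0)
      p_inf + spec$n_redundant + seq_len(spec$n_noise) else integer(0))
  fm
}

## internal: smooth white noise with a box kernel, same-size output
smooth_noise <- function(h, w, sigma, rng, passes = 2L) {
  x <- matrix(rng$rnorm(h * w, sd = sigma), h, w)
  box <- matrix(1 / 9, 3, 3)
  for (i in seq_len(passes)) {
    pad <- matrix(0, h + 2L, w + 2L)
    pad[2:(h + 1L), 2:(w + 1L)] <- x
    pad[1, ] <- pad[2, ]; pad[h + 2L, ] <- pad[h + 1L, ]
    pad[, 1] <- pad[, 2]; pad[, w + 2L] <- pad[, w + 1L]
    x <- conv2d_valid(pad, box)
  }
  x
}

#' Generate toy lesion images
#'
#' Each image is a textured background (smoothed Gaussian noise around a
#' mid-gray level) plus one elliptical "lesion" whose intensity offset,
#' per-channel coloring, eccentricity and internal sinusoidal texture depend
#' on the class. Every class-dependent term is multiplied by `contrast`, so
#' at `contrast = 0` the lesion is statistically invisible and the labels
#' carry no signal. These are deliberately schematic stand-ins for
#' dermoscopy images — enough structure to exercise enhancement, feature
#' extraction and classification end to end. Bit-reproducible per seed.
#'
#' @param n Number of images.
#' @param n_classes Number of classes (cycled over images).
#' @param size Image side length in pixels (>= 16).
#' @param contrast Lesion/background contrast in [0, 1].
#' @param seed Integer seed.
#' @return List with `images` (list of size x size x 3 arrays, 0-255),
#'   `labels` (factor) and `masks` (list of logical lesion masks).
#' @export
make_images <- function(n, n_classes = 7L, size = 32L, contrast = 1,
                        seed = 0L) {
  if (size < 16L) stop("size must be at least 16")
  stopifnot(contrast >= 0, contrast <= 1, n >= 1, n_classes >= 2)
  rng <- local_rng(seed)
  labels <- factor(sprintf("class%d", rep_len(seq_len(n_classes), n)),
                   levels = sprintf("class%d", seq_len(n_classes)))
  # fixed per-class appearance parameters
  offs <- seq(-60, 60, length.out = n_classes)            # intensity offset
  ecc <- seq(0.5, 1, length.out = n_classes)              # axis ratio
  freq <- seq(0.2, 0.9, length.out = n_classes)           # texture frequency
  hue <- matrix(rng$runif(n_classes * 3, -0.4, 0.4), n_classes, 3)
  co <- (seq_len(size) - (size + 1) / 2)
  images <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- as.integer(labels[i])
    cx <- rng$runif(1, -size / 8, size / 8)
    cy <- rng$runif(1, -size / 8, size / 8)
    theta <- rng$runif(1, 0, pi)
    r <- size * rng$runif(1, 0.22, 0.3)
    u <- outer(co - cy, rep(1, size)) ; v <- outer(rep(1, size), co - cx)
    ur <- u * cos(theta) + v * sin(theta)
    vr <- -u * sin(theta) + v * cos(theta)
    mask <- (ur / r)^2 + (vr / (r * ecc[cls]))^2 <= 1
    tex <- sin(freq[cls] * ur) * sin(freq[cls] * vr) * 15
    img <- array(0, dim = c(size, size, 3))
    for (ch in 1:3) {
      bg <- 110 + smooth_noise(size, size, 12, rng)
      lesion_term <- contrast * (offs[cls] * (1 + hue[cls, ch]) + tex)
      plane <- bg + mask * lesion_term
      img[, , ch] <- pmin(pmax(plane, 0), 255)
    }
    images[[i]] <- img
    masks[[i]] <- mask
  }
  list(images = images, labels = labels, masks = masks)
}
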