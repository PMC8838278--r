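# Independent oracles used across tests: plain scalar loops and textbook
# closed forms, deliberately written without reusing package internals.

# elementwise re-evaluation of the enhancement transform, one channel
enhance_oracle_channel <- function(x, ref) {
  n <- length(x)
  md <- sum(abs(x - ref)) / n
  mu <- sum(x) / n
  s <- sqrt(sum((x - mu)^2) / (n - 1))
  sk <- if (is.na(s) || s == 0) 0 else sum((x - mu)^3) / ((n - 1) * s^3)
  out <- abs(abs(md + x) - sk)
  pmin(pmax(out, 0), 255)
}

# brute-force quadruple-loop valid convolution
conv_oracle <- function(image, kernel) {
  oh <- nrow(image) - nrow(kernel) + 1L
  ow <- ncol(image) - ncol(kernel) + 1L
  out <- matrix(0, oh, ow)
  for (i in seq_len(oh)) for (j in seq_len(ow)) {
    acc <- 0
    for (a in seq_len(nrow(kernel))) for (b in seq_len(ncol(kernel)))
      acc <- acc + kernel[a, b] * image[i + a - 1L, j + b - 1L]
    out[i, j] <- acc
  }
  out
}

# whitened-SVD canonical correlations (classical two-set CCA oracle)
cca_svd_oracle <- function(x, y) {
  cx <- scale(x, scale = FALSE); cy <- scale(y, scale = FALSE)
  n <- nrow(x)
  zxx <- crossprod(cx) / (n - 1); zyy <- crossprod(cy) / (n - 1)
  zxy <- crossprod(cx, cy) / (n - 1)
  isqrt <- function(z) {
    e <- eigen(z, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), nrow(z)) %*% t(e$vectors)
  }
  svd(isqrt(zxx) %*% zxy %*% isqrt(zyy))$d
}

# discrete entropy of a probability vector, nats
entropy_oracle <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }

# per-column between/within variance ratio (one-way ANOVA style F statistic)
anova_f_oracle <- function(values, labels) {
  apply(values, 2, function(x) {
    summary(stats::aov(x ~ labels))[[1]][["F value"]][1]
  })
}

random_image <- function(h, w, channels = 1L, max_val = 255) {
  if (channels == 1L) matrix(stats::runif(h * w, 0, max_val), h, w)
  else array(stats::runif(h * w * channels, 0, max_val), dim = c(h, w, channels))
}

small_feature_set <- function(seed = 0L, n = 120L, n_classes = 3L) {
  make_features(synthetic_spec(n_samples = n, n_classes = n_classes,
                               n_informative = 4L, n_redundant = 0L,
                               n_noise = 12L, class_separation = 3,
                               seed = seed))
}
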