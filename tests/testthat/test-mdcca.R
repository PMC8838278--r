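test_that("covariance blocks match a direct-summation oracle", {
  set.seed(20)
  x <- matrix(rnorm(60), 20, 3); y <- matrix(rnorm(40), 20, 2)
  b <- covariance_blocks(list(x, y))
  cx <- sweep(x, 2, colMeans(x)); cy <- sweep(y, 2, colMeans(y))
  oracle_xy <- matrix(0, 3, 2)
  for (i in 1:20) oracle_xy <- oracle_xy + tcrossprod(cx[i, ], cy[i, ])
  expect_equal(b$cross[["1_2"]], oracle_xy / 19, tolerance = 1e-10)
  expect_equal(b$within[[1]], crossprod(cx) / 19, tolerance = 1e-10)
  # a set against itself: cross block equals within block
  bb <- covariance_blocks(list(x, x))
  expect_equal(bb$cross[["1_2"]], bb$within[[1]], tolerance = 1e-12)
  expect_error(covariance_blocks(list(x, y[1:10, ])), "row-count")
})

test_that("identical sets give canonical correlations of one", {
  set.seed(21)
  x <- matrix(rnorm(200), 50, 4)
  fit <- mdcca(list(x, x))
  expect_true(all(abs(fit$correlations - 1) < 1e-6))
})

test_that("independent sets give a small leading canonical correlation", {
  set.seed(7)
  x <- matrix(rnorm(3000), 1000, 3); y <- matrix(rnorm(3000), 1000, 3)
  fit <- mdcca(list(x, y))
  expect_true(fit$correlations[1] < 0.15)
})

test_that("eigen-solve correlations match the whitened-SVD oracle", {
  set.seed(22)
  for (i in 1:5) {
    x <- matrix(rnorm(250), 50, 5); y <- matrix(rnorm(200), 50, 4)
    y[, 1] <- x[, 2] * 0.7 + rnorm(50, sd = 0.5)
    fit <- mdcca(list(x, y), d = 4)
    oracle <- cca_svd_oracle(x, y)
    expect_equal(fit$correlations, oracle[1:4], tolerance = 1e-6)
    # eigenvalues are the squared singular values of the whitened cross
    # block, up to the ridge-order perturbation of the within blocks
    expect_equal(fit$eigenvalues, oracle[1:4]^2, tolerance = 1e-5)
    expect_true(all(diff(fit$correlations) <= 1e-6))
    expect_true(all(fit$correlations >= 0 & fit$correlations <= 1 + 1e-8))
  }
})

test_that("canonical correlations are invariant to per-set affine scaling", {
  set.seed(23)
  x <- matrix(rnorm(250), 50, 5); y <- matrix(rnorm(150), 50, 3)
  f1 <- mdcca(list(x, y), d = 3)
  f2 <- mdcca(list(x %*% diag(c(10, 0.2, 3, 1, 5)) + 7, y * 0.01 - 2), d = 3)
  expect_equal(f1$correlations, f2$correlations, tolerance = 1e-6)
})

test_that("three-set fusion solves the multiset eigenproblem", {
  set.seed(24)
  z <- matrix(rnorm(150), 50, 3)
  x <- z + matrix(rnorm(150, sd = 0.5), 50)
  y <- z + matrix(rnorm(150, sd = 0.5), 50)
  w <- matrix(rnorm(200), 50, 4)
  fit <- mdcca(list(x, y, w))
  expect_equal(fit$m, 3L)
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  expect_equal(length(fit$projections), 3L)
  fused <- fuse_sets(fit, list(x, y, w))
  expect_equal(ncol(fused$fused), 3L * fit$d)
})

test_that("fusion projects, concatenates and sorts by variance", {
  set.seed(25)
  x <- matrix(rnorm(300), 50, 6); y <- matrix(rnorm(250), 50, 5)
  fit <- mdcca(list(x, y), d = 3)
  out <- fuse_sets(fit, list(x, y))
  expect_equal(ncol(out$fused), 6L)
  v <- apply(out$fused, 2, var)
  expect_true(all(diff(v) <= 1e-12))
  # projected variates have unit variance on the training data
  expect_equal(unname(v), rep(1, 6), tolerance = 1e-6)
  expect_error(fuse_sets(fit, list(x[, 1:3], y)), "shape mismatch")
  expect_error(mdcca(list(x, y), d = 10), "exceeds")
})

test_that("redundancy pruning drops correlated and duplicate columns", {
  set.seed(26)
  m <- matrix(rnorm(200), 50, 4)
  m <- m[, order(apply(m, 2, var), decreasing = TRUE)]
  dup <- cbind(m, m[, 2])
  r <- remove_redundant(dup, 0.95)
  expect_equal(r$kept_columns, 1:4)
  # near-copy: col5 = 0.999 col1 + tiny noise
  near <- cbind(m, 0.999 * m[, 1] + rnorm(50, sd = 1e-4))
  r2 <- remove_redundant(near, 0.95)
  expect_false(5L %in% r2$kept_columns)
  # orthogonal columns all survive
  q <- qr.Q(qr(matrix(rnorm(100), 20, 5)))
  r3 <- remove_redundant(q, 0.95)
  expect_equal(r3$kept_columns, 1:5)
  # the first column is never dropped; survivors are pairwise below threshold
  expect_true(1L %in% r2$kept_columns)
  cc <- abs(stats::cor(r2$pruned))
  expect_true(all(cc[upper.tri(cc)] <= 0.95))
})
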