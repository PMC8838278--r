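test_that("valid-mode convolution matches the brute-force loop", {
  expect_equal(conv2d_valid(matrix(1, 3, 3), matrix(1, 2, 2)),
               matrix(4, 2, 2))
  img <- matrix(rnorm(30), 5, 6)
  expect_equal(conv2d_valid(img, matrix(1, 1, 1)), img)
  delta <- matrix(0, 2, 2); delta[1, 1] <- 1
  expect_equal(conv2d_valid(img, delta), img[1:4, 1:5])
  set.seed(11)
  for (i in 1:10) {
    a <- matrix(rnorm(64), 8, 8)
    k <- matrix(rnorm(9), 3, 3)
    expect_equal(conv2d_valid(a, k), conv_oracle(a, k))
  }
  expect_error(conv2d_valid(matrix(1, 2, 2), matrix(1, 3, 3)), "larger")
})

test_that("relu clamps negatives and is idempotent", {
  expect_equal(relu(c(-1, 0, 2)), c(0, 0, 2))
  expect_equal(relu(c(-5, -1)), c(0, 0))
  x <- abs(rnorm(10))
  expect_equal(relu(x), x)
  y <- rnorm(10)
  expect_equal(relu(relu(y)), relu(y))
})

test_that("pooling obeys the output-dimension formula", {
  # W2 = (W1 - G)/Z + 1
  out <- pool2d(matrix(rnorm(16), 4, 4), window = 2, stride = 2)
  expect_equal(dim(out), c(2L, 2L))
  expect_equal(pool2d(matrix(1:4, 2, 2, byrow = TRUE), 2, 2, "max"),
               matrix(4, 1, 1))
  expect_equal(pool2d(matrix(1:4, 2, 2, byrow = TRUE), 2, 2, "average"),
               matrix(2.5, 1, 1))
  expect_equal(pool2d(matrix(1:4, 2, 2, byrow = TRUE), 2, 2, "min"),
               matrix(1, 1, 1))
  for (w1 in c(4, 6, 10)) for (g in c(2, 4)) {
    z <- 2
    if ((w1 - g) %% z == 0) {
      got <- pool2d(matrix(0, w1, w1), g, z)
      expect_equal(nrow(got), (w1 - g) / z + 1)
    }
  }
  expect_error(pool2d(matrix(0, 5, 5), 2, 2), "stride")
  expect_error(pool2d(matrix(0, 3, 3), 4, 1), "window")
})

test_that("softmax is a stable probability map", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  set.seed(2)
  for (i in 1:10) {
    q <- rnorm(sample(2:8, 1), sd = 10)
    p <- softmax(q)
    expect_true(all(p > 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(softmax(q + 5), p, tolerance = 1e-12)
  }
  expect_equal(softmax(c(1000, 1000)), c(0.5, 0.5))  # no overflow
  expect_error(softmax(numeric(0)), "empty")
})

test_that("toy backbone is deterministic with the documented width", {
  imgs <- make_images(4, n_classes = 2, size = 32, seed = 3)$images
  fm1 <- extract_features(imgs, labels = c("a", "b", "a", "b"))
  fm2 <- extract_features(imgs, labels = c("a", "b", "a", "b"))
  expect_identical(fm1$values, fm2$values)
  expect_equal(ncol(fm1$values), 4 * 4 * 3 * 3)  # grid^2 x stats x channels
  # identical images give identical rows
  fm3 <- extract_features(list(imgs[[1]], imgs[[1]]))
  expect_identical(fm3$values[1, ], fm3$values[2, ])
  # constant image: all per-patch std and amd features are zero
  fmc <- extract_features(list(array(100, dim = c(32, 32, 3))))
  stats_idx <- rep(c("mean", "sd", "amd"), times = 48)
  expect_true(all(fmc$values[1, stats_idx != "mean"] == 0))
})

test_that("external backbone adapters are validated", {
  imgs <- list(random_image(16, 16), random_image(16, 16))
  good <- backbone_spec("external",
                        extractor = function(x) matrix(1, length(x), 5))
  fm <- extract_features(imgs, labels = c("a", "b"), backbone = good)
  expect_equal(dim(fm$values), c(2L, 5L))
  bad_rows <- backbone_spec("external", extractor = function(x) matrix(1, 1, 5))
  expect_error(extract_features(imgs, backbone = bad_rows), "one feature row")
  wrong_width <- backbone_spec("external",
                               extractor = function(x) matrix(1, length(x), 5),
                               expected_width = 1056L)
  expect_error(extract_features(imgs, backbone = wrong_width), "1056")
  expect_error(backbone_spec("external"), "extractor")
})
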