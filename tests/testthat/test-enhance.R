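test_that("absolute mean deviation matches direct evaluation", {
  expect_equal(compute_amd(c(0, 2, 4, 6), 3), 2)
  expect_equal(compute_amd(rep(7, 4), 7), 0)
  expect_equal(compute_amd(5, 5), 0)
  expect_error(compute_amd(numeric(0), 0), "empty image")
  # translation covariance: amd(x + delta, m + delta) = amd(x, m)
  set.seed(1)
  for (i in 1:10) {
    x <- runif(20, 0, 255); m <- runif(1, 0, 255); delta <- runif(1, -50, 50)
    expect_equal(compute_amd(x + delta, m + delta), compute_amd(x, m))
  }
})

test_that("skewness follows the sample (n-1) convention with zero-sd guard", {
  expect_equal(compute_skewness(c(1, 2, 3)), 0)
  expect_equal(compute_skewness(c(7, 7, 7)), 0)
  expect_equal(compute_skewness(c(0, 0, 0, 4)), 1)
  expect_equal(compute_skewness(5), 0)
  expect_error(compute_skewness(numeric(0)), "empty image")
})

test_that("single-image enhancement matches hand-derived values", {
  x <- matrix(c(0, 100, 100, 200), 2, 2)
  expect_equal(enhance_image(x, 100), matrix(c(50, 150, 150, 250), 2, 2))
  # constant image with matching reference is a fixed point
  const <- matrix(42, 3, 3)
  expect_equal(enhance_image(const, 42), const)
  expect_error(enhance_image(random_image(4, 4, 3), c(1, 2)), "per channel")
})

test_that("enhancement equals the scalar-loop oracle on random images", {
  set.seed(7)
  for (i in 1:20) {
    img <- random_image(sample(3:12, 1), sample(3:12, 1))
    ref <- runif(1, 0, 255)
    expect_equal(enhance_image(img, ref),
                 matrix(enhance_oracle_channel(as.vector(img), ref),
                        nrow(img), ncol(img)),
                 tolerance = 1e-9)
  }
  # rgb: channels are independent
  img <- random_image(6, 5, 3)
  ref <- runif(3, 0, 255)
  out <- enhance_image(img, ref)
  for (ch in 1:3)
    expect_equal(out[, , ch],
                 matrix(enhance_oracle_channel(as.vector(img[, , ch]), ref[ch]), 6, 5),
                 tolerance = 1e-9)
  expect_true(all(out >= 0 & out <= 255))
  expect_equal(dim(out), dim(img))
})

test_that("dataset enhancement pools the reference mean over all images", {
  img <- random_image(5, 5)
  single <- enhance_dataset(list(img))
  expect_equal(single$reference_mean, mean(img))
  # two constant images: pooled reference is 100, outputs are 100 and 255
  res <- enhance_dataset(list(matrix(0, 4, 4), matrix(200, 4, 4)))
  expect_equal(res$reference_mean, 100)
  expect_equal(res$images[[1]], matrix(100, 4, 4))
  expect_equal(res$images[[2]], matrix(255, 4, 4))  # |100 + 200| clipped
  # duplicated images enhance identically
  dup <- enhance_dataset(list(img, img, img))
  expect_identical(dup$images[[1]], dup$images[[2]])
  expect_identical(dup$images[[2]], dup$images[[3]])
  expect_error(enhance_dataset(list()), "empty")
  expect_error(enhance_dataset(list(random_image(4, 4, 3), random_image(4, 4))),
               "mixed channel")
})

test_that("enhancement statistics are reported per channel", {
  img <- random_image(6, 6, 3)
  st <- enhancement_stats(img, c(10, 20, 30))
  expect_equal(nrow(st), 3)
  expect_equal(st$dataset_mean, c(10, 20, 30))
  expect_true(all(st$amd >= 0))
})

test_that("images round-trip through PNG at 8-bit precision", {
  img <- round(random_image(8, 9, 3))
  path <- tempfile(fileext = ".png")
  write_image(img, path)
  back <- read_image(path)
  expect_equal(dim(back), dim(img))
  expect_true(max(abs(back - img)) <= 0.5)
  unlink(path)
})
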