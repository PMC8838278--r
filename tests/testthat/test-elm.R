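test_that("hidden parameters are seeded draws in [-1, 1]", {
  h1 <- init_hidden(20, 7, seed = 5)
  h2 <- init_hidden(20, 7, seed = 5)
  expect_identical(h1, h2)
  expect_true(all(abs(h1$weights) <= 1), all(abs(h1$biases) <= 1))
  h3 <- init_hidden(20, 7, seed = 6)
  expect_false(identical(h1$weights, h3$weights))
  expect_error(init_hidden(0, 3), "at least 1")
})

test_that("the hidden matrix applies Gaussian squashing to the affine form", {
  x <- matrix(c(1, 2), 1, 2)
  # zero weights and bias: g(0) = 1
  expect_equal(hidden_matrix(x, matrix(0, 3, 2), rep(0, 3)),
               matrix(1, 1, 3))
  # w.a + c = 1 gives e^-1
  expect_equal(hidden_matrix(matrix(1, 1, 1), matrix(1, 1, 1), 0)[1, 1],
               exp(-1))
  set.seed(30)
  h <- hidden_matrix(matrix(rnorm(50), 10, 5), matrix(runif(20, -1, 1), 4, 5),
                     runif(4, -1, 1))
  expect_true(all(h > 0 & h <= 1))
  expect_error(hidden_matrix(matrix(0, 2, 3), matrix(0, 4, 2), rep(0, 4)),
               "dimension mismatch")
})

test_that("a square hidden matrix interpolates the training set", {
  set.seed(31)
  x <- matrix(rnorm(50), 10, 5)
  y <- factor(rep(c("u", "v"), 5))
  fit <- elm(x, y, hidden_nodes = 10, seed = 1)
  expect_equal(fit$training_accuracy, 100)
  expect_equal(predict(fit, x), y)
})

test_that("output weights solve the least-squares problem", {
  set.seed(32)
  for (i in 1:5) {
    x <- matrix(rnorm(30 * 8), 30, 8)
    y <- factor(sample(c("a", "b", "c"), 30, replace = TRUE))
    fit <- elm(x, y, hidden_nodes = 20, seed = i)
    # rebuild H exactly as the model sees it, then solve by QR independently
    xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
    h <- hidden_matrix(xs, fit$input_weights, fit$biases)
    b <- matrix(0, 30, 3); b[cbind(1:30, as.integer(y))] <- 1
    beta_qr <- qr.solve(h, b)
    expect_equal(coef(fit), beta_qr, tolerance = 1e-8)
    # the solution beats random perturbations in residual norm
    res0 <- norm(h %*% coef(fit) - b, "F")
    for (j in 1:20) {
      pert <- coef(fit) + matrix(rnorm(60, sd = 0.05), 20, 3)
      expect_true(res0 <= norm(h %*% pert - b, "F") + 1e-12)
    }
  }
})

test_that("duplicating every training sample leaves the solution unchanged", {
  set.seed(33)
  x <- matrix(rnorm(40), 10, 4)
  y <- factor(rep(c("a", "b"), 5))
  f1 <- elm(x, y, hidden_nodes = 6, seed = 2)
  f2 <- elm(rbind(x, x), c(y, y), hidden_nodes = 6, seed = 2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("training accuracy does not decrease with hidden-layer size", {
  fm <- small_feature_set(seed = 9, n = 60)
  med_acc <- sapply(c(5, 15, 30), function(L) {
    stats::median(sapply(1:5, function(s)
      elm(fm, hidden_nodes = L, seed = s)$training_accuracy))
  })
  expect_true(all(diff(med_acc) >= 0))
})

test_that("prediction is invariant to consistent feature permutation", {
  set.seed(34)
  x <- matrix(rnorm(100), 20, 5)
  y <- factor(rep(c("a", "b"), 10))
  xt <- matrix(rnorm(50), 10, 5)
  hid <- init_hidden(8, 5, seed = 3)
  perm <- c(3, 1, 5, 2, 4)
  f1 <- elm(x, y, seed = 3, hidden = hid)
  f2 <- elm(x[, perm], y, seed = 3,
            hidden = list(weights = hid$weights[, perm], biases = hid$biases))
  expect_equal(predict(f1, xt), predict(f2, xt[, perm]))
})

test_that("models survive a JSON round trip", {
  set.seed(35)
  x <- matrix(rnorm(60), 15, 4)
  y <- factor(rep(c("a", "b", "c"), 5))
  fit <- elm(x, y, hidden_nodes = 7, seed = 4)
  path <- tempfile(fileext = ".json")
  write_elm(fit, path)
  back <- read_elm(path)
  expect_equal(predict(back, x), predict(fit, x))
  unlink(path)
})

test_that("metrics follow the precision + FDR = 100 convention", {
  m <- evaluate_predictions(c("a", "b"), c("a", "b"))
  expect_equal(m$accuracy, 100)
  expect_equal(m$precision, 100)
  expect_equal(m$fdr, 0)
  # hand-counted two-class case
  m2 <- evaluate_predictions(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(m2$accuracy, 75)
  expect_equal(unname(m2$per_class_precision), c(1 / 2, 1))
  expect_equal(m2$precision, 75)
  expect_equal(m2$fdr, 25)
  # the convention holds for arbitrary predictions
  set.seed(36)
  for (i in 1:10) {
    cl <- letters[1:4]
    m3 <- evaluate_predictions(sample(cl, 50, TRUE), sample(cl, 50, TRUE), cl)
    expect_equal(m3$precision + m3$fdr, 100)
    expect_equal(sum(rowSums(m3$confusion)), 50)
  }
  # sample order does not matter
  p <- sample(letters[1:3], 30, TRUE); t <- sample(letters[1:3], 30, TRUE)
  o <- sample(30)
  expect_equal(evaluate_predictions(p, t)$accuracy,
               evaluate_predictions(p[o], t[o])$accuracy)
  expect_error(evaluate_predictions(c("a", "z"), c("a", "b"), c("a", "b")),
               "unknown label")
})

test_that("degenerate training inputs are rejected", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(elm(x, rep("one", 10)), "two classes")
  expect_error(elm(x[1, , drop = FALSE], "a"), "two classes")
})
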