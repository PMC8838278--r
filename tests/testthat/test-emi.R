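test_that("fuzzy entropy follows the membership formula", {
  expect_equal(fuzzy_entropy(0.5), log(2))
  expect_equal(fuzzy_entropy(c(0, 1, 0, 1)), 0)      # crisp set
  x <- runif(10)
  expect_equal(fuzzy_entropy(x, K = 2), 2 * fuzzy_entropy(x, K = 1))
  # maximal at uniform 0.5 membership
  expect_true(fuzzy_entropy(rep(0.5, 10)) >= fuzzy_entropy(runif(10)))
  expect_error(fuzzy_entropy(c(0.5, 1.2)), "0, 1")
})

test_that("joint and conditional entropy match direct summation", {
  r <- joint_and_conditional_entropy(matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(r$joint_entropy, log(2))
  expect_equal(r$conditional_entropy, 0)
  r <- joint_and_conditional_entropy(matrix(0.25, 2, 2))
  expect_equal(r$joint_entropy, log(4))
  expect_equal(r$conditional_entropy, log(2))
  r <- joint_and_conditional_entropy(matrix(c(1, 0, 0, 0), 2, 2))
  expect_equal(r$joint_entropy, 0)
  expect_equal(r$conditional_entropy, 0)
  expect_error(joint_and_conditional_entropy(matrix(0.3, 2, 2)), "sum to 1")
})

test_that("mutual information obeys the entropy identity", {
  x <- rep(c(0, 1), 50)
  expect_equal(mutual_information(x, x), log(2))   # I(X;X) = H(X)
  # complete cross design: joint = product of marginals, I = 0 exactly
  g <- expand.grid(a = 1:4, b = 1:3)
  expect_equal(mutual_information(g$a, g$b), 0)
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(200); y <- x + rnorm(200)
    expect_equal(mutual_information(x, y), mutual_information(y, x))
    # I = H(X) + H(Y) - H(X,Y) on the same empirical table
    xb <- skinfuse:::discretize(x, 16); yb <- skinfuse:::discretize(y, 16)
    joint <- table(xb, yb); joint <- joint / sum(joint)
    hx <- entropy_oracle(rowSums(joint))
    hy <- entropy_oracle(colSums(joint))
    hxy <- entropy_oracle(as.vector(joint))
    expect_equal(mutual_information(x, y), hx + hy - hxy, tolerance = 1e-10)
    expect_true(mutual_information(x, y) >= 0)
  }
  expect_error(mutual_information(1:5, 1:4), "length mismatch")
})

test_that("the filter ranks a label-matched feature above noise", {
  top_rank <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 500
    lab <- factor(rep(c("a", "b"), n / 2))
    informative <- as.numeric(lab == "a") + rnorm(n, sd = 0.3)
    noise <- rnorm(n)
    fm <- feature_matrix(cbind(informative, noise), lab)
    sel <- emi_select(fm)
    if (which.max(sel$scores) == 1L) top_rank <- top_rank + 1
  }
  expect_true(top_rank >= 9)
})

test_that("the filter is deterministic and honours degeneracy guards", {
  fm <- small_feature_set(seed = 5)
  s1 <- emi_select(fm); s2 <- emi_select(fm)
  expect_identical(s1$mask, s2$mask)
  expect_identical(s1$scores, s2$scores)
  # a constant column scores zero and is never selected
  v <- cbind(fm$values, const = 5)
  s3 <- emi_select(feature_matrix(v, fm$labels))
  expect_equal(s3$scores[ncol(v)], 0)
  expect_false(s3$mask[ncol(v)])
  # duplicated informative column gets its twin's score exactly
  v2 <- cbind(fm$values, twin = fm$values[, 1])
  s4 <- emi_select(feature_matrix(v2, fm$labels))
  expect_equal(s4$scores[ncol(v2)], s4$scores[1])
  # all-constant matrix is rejected
  expect_error(emi_select(feature_matrix(matrix(1, 10, 3),
                                         rep(c("a", "b"), 5))),
               "no informative variance")
  expect_error(emi_select(feature_matrix(fm$values,
                                         rep("one", nrow(fm$values)))),
               "two classes")
})
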