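test_that("feature centering removes column means and reports them", {
  r <- center_features(matrix(c(1, 3), 2, 1))
  expect_equal(as.numeric(r$X), c(-1, 1))
  expect_equal(unname(r$means), 2)

  Xc <- matrix(c(-1, 1, 0.5, -0.5), 2, 2)
  expect_equal(center_features(Xc)$X, Xc)

  r <- center_features(matrix(5, 3, 1))
  expect_equal(as.numeric(r$X), c(0, 0, 0))

  expect_error(center_features(matrix(numeric(0), 0, 2)), "empty")
})

test_that("row L2 normalization yields unit rows and rejects zero rows", {
  expect_equal(as.numeric(l2_normalize_rows(matrix(c(3, 4), 1, 2))),
               c(0.6, 0.8))
  u <- matrix(c(1, 0), 1, 2)
  expect_equal(l2_normalize_rows(u), u)
  expect_error(l2_normalize_rows(rbind(c(1, 2), c(0, 0))), "row.*2")
})

test_that("target centering removes the mean and keeps it for reporting", {
  r <- center_targets(c(1, 2, 3))
  expect_equal(r$y, c(-1, 0, 1))
  expect_equal(r$mean, 2)
  expect_equal(center_targets(c(-1, 0, 1))$y, c(-1, 0, 1))
  expect_equal(center_targets(7), list(y = 0, mean = 7))
  expect_error(center_targets(numeric(0)), "empty")
})

test_that("sufficient statistics match their definitions", {
  s0 <- sufficient_stats(matrix(numeric(0), 0, 2), numeric(0))
  expect_equal(s0$nxx, matrix(0, 2, 2))
  expect_equal(s0$nxy, c(0, 0))
  expect_equal(s0$nyy, 0)
  expect_equal(s0$n, 0L)

  s1 <- sufficient_stats(matrix(c(1, 2), 1, 2), 3)
  expect_equal(s1$nxx, rbind(c(1, 2), c(2, 4)))
  expect_equal(s1$nxy, c(3, 6))
  expect_equal(s1$nyy, 9)
  expect_false(s1$is_noisy)
})

test_that("statistics are additive over dataset concatenation", {
  for (seed in 1:20) {
    a <- random_dataset(11, 4, seed = seed)
    b <- random_dataset(7, 4, seed = seed + 1000)
    ab <- labeled_dataset(rbind(a$X, b$X), c(a$y, b$y))
    sum_parts <- combine_stats(sufficient_stats(a), sufficient_stats(b))
    whole <- sufficient_stats(ab)
    expect_equal(sum_parts$nxx, whole$nxx, tolerance = 1e-12)
    expect_equal(sum_parts$nxy, whole$nxy, tolerance = 1e-12)
    expect_equal(sum_parts$nyy, whole$nyy, tolerance = 1e-12)
    expect_equal(sum_parts$n, whole$n)
  }
})

test_that("combine_stats has identity, associativity and commutativity", {
  a <- sufficient_stats(random_dataset(9, 3, seed = 1))
  b <- sufficient_stats(random_dataset(5, 3, seed = 2))
  cc <- sufficient_stats(random_dataset(6, 3, seed = 3))
  zero <- sufficient_stats(matrix(numeric(0), 0, 3), numeric(0))

  expect_equal(combine_stats(a), a)
  expect_equal(combine_stats(a, zero)$nxx, a$nxx)
  expect_equal(combine_stats(combine_stats(a, b), cc)$nxx,
               combine_stats(a, combine_stats(b, cc))$nxx, tolerance = 1e-12)
  expect_equal(combine_stats(a, b)$nxy, combine_stats(b, a)$nxy,
               tolerance = 1e-12)
  expect_error(combine_stats(a, sufficient_stats(random_dataset(4, 2))),
               "dimension mismatch")
})

test_that("clean statistics are PSD with nonnegative nyy", {
  for (seed in 1:100) {
    s <- sufficient_stats(random_dataset(8, 3, seed = seed))
    expect_true(all(eigen(s$nxx, symmetric = TRUE,
                          only.values = TRUE)$values >= -1e-10))
    expect_gte(s$nyy, 0)
    expect_identical(s$nxx, t(s$nxx))
  }
})

test_that("labeled_dataset drops missing targets and rejects missing inputs", {
  d <- labeled_dataset(matrix(1:6, 3, 2), c(1, NA, 3))
  expect_equal(d$n, 2L)
  expect_error(labeled_dataset(matrix(c(1, NA), 1, 2), 1), "missing")
  expect_error(labeled_dataset(matrix(1, 2, 1), 1), "must equal")
})

test_that("preprocessing is a fixpoint on centered unit-norm data", {
  v <- c(3, 4) / 5
  X <- rbind(v, -v)  # column means 0, rows unit norm
  d <- labeled_dataset(X, c(1, -1))
  pp <- preprocess(d)
  expect_equal(pp$data$X, X, ignore_attr = TRUE)
  expect_equal(pp$data$y, c(1, -1))
  # training transform applies to new data
  expect_equal(apply_preprocess(X, pp), X, ignore_attr = TRUE)
})
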