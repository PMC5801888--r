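test_that("privacy budget validates its split", {
  b <- privacy_budget(2, c(0.35, 0.60, 0.05))
  expect_equal(b$p1 * b$epsilon + b$p2 * b$epsilon + b$p3 * b$epsilon,
               b$epsilon)
  expect_error(privacy_budget(2, c(0.5, 0.5, 0.1)), "sum to 1")
  expect_error(privacy_budget(2, c(0.5, 0.5, 0)), "positive")
  expect_error(privacy_budget(-1, c(1, 1, 1) / 3), "positive")
})

test_that("noise scales follow the sensitivity formulas", {
  s <- laplace_scales(10, bounds(1, 1), privacy_budget(2, c(0.35, 0.60, 0.05)))
  expect_equal(s$s_xx, 110 / 0.7)    # 157.142857...
  expect_equal(s$s_xy, 20 / 1.2)     # 16.666667...
  expect_equal(s$s_yy, 10)

  s1 <- laplace_scales(1, bounds(1, 1), privacy_budget(1, rep(1, 3) / 3))
  expect_equal(c(s1$s_xx, s1$s_xy, s1$s_yy), c(6, 6, 3))

  s2 <- laplace_scales(10, bounds(1, 1), privacy_budget(4, c(0.35, 0.60, 0.05)))
  expect_equal(c(s2$s_xx, s2$s_xy, s2$s_yy),
               c(s$s_xx, s$s_xy, s$s_yy) / 2)
})

test_that("scales are monotone in budget, dimension and bounds", {
  base <- laplace_scales(5, bounds(1, 1), privacy_budget(2, c(0.3, 0.4, 0.3)))
  more_eps <- laplace_scales(5, bounds(1, 1),
                             privacy_budget(3, c(0.3, 0.4, 0.3)))
  bigger_d <- laplace_scales(8, bounds(1, 1),
                             privacy_budget(2, c(0.3, 0.4, 0.3)))
  bigger_b <- laplace_scales(5, bounds(2, 1.5),
                             privacy_budget(2, c(0.3, 0.4, 0.3)))
  more_p1 <- laplace_scales(5, bounds(1, 1),
                            privacy_budget(2, c(0.5, 0.3, 0.2)))
  expect_true(all(unlist(more_eps[1:3]) < unlist(base[1:3])))
  expect_gt(bigger_d$s_xx, base$s_xx)
  expect_gt(bigger_d$s_xy, base$s_xy)
  expect_true(all(unlist(bigger_b[1:3]) > unlist(base[1:3])))
  expect_lt(more_p1$s_xx, base$s_xx)
})

test_that("perturbation keeps symmetry, n, and is seed-deterministic", {
  st <- sufficient_stats(random_dataset(30, 4, seed = 3))
  sc <- laplace_scales(4, bounds(1, 1), privacy_budget(2, c(0.35, 0.6, 0.05)))
  n1 <- privlr:::with_seed(11, perturb_stats(st, sc))
  n2 <- privlr:::with_seed(11, perturb_stats(st, sc))
  n3 <- privlr:::with_seed(12, perturb_stats(st, sc))
  expect_identical(n1$nxx, t(n1$nxx))
  expect_identical(n1$nxx, n2$nxx)
  expect_false(identical(n1$nxx, n3$nxx))
  expect_equal(n1$n, st$n)
  expect_true(n1$is_noisy)
  expect_error(perturb_stats(n1, sc), "double")
})

test_that("injected noise has Laplace moments", {
  # scale = mean absolute deviation; variance = 2 * scale^2
  privlr:::with_seed(42, {
    x <- rlaplace(1e5, scale = 3)
    expect_lt(abs(mean(x)), 3 * sqrt(2) * 3 / sqrt(1e5) * 3)
    expect_lt(abs(mean(abs(x)) - 3) / 3, 0.05)
    expect_lt(abs(var(x) - 18) / 18, 0.05)

    # through perturb_stats on a scalar statistic (d = 1)
    st <- sufficient_stats(matrix(0, 1, 1), 0)
    sc <- laplace_scales(1, bounds(1, 1), privacy_budget(1, rep(1, 3) / 3))
    draws <- replicate(2e4, perturb_stats(st, sc)$nyy)  # scale 3
    expect_lt(abs(mean(draws)), 3 * (3 * sqrt(2)) / sqrt(2e4))
    expect_lt(abs(mean(abs(draws)) - 3) / 3, 0.05)
  })
})

test_that("empirical sensitivity never exceeds the calibrated numerators", {
  privlr:::with_seed(5, {
    b <- bounds(0.8, 1.3)
    d <- 4
    mx <- check_sensitivity(d, b, n_trials = 2000)
    expect_lte(mx[["d_nxx"]], (d^2 + d) * b$bx^2)
    expect_lte(mx[["d_nxy"]], 2 * d * b$bx * b$by)
    expect_lte(mx[["d_nyy"]], b$by^2)
    # the adversarial pair attains the nxy bound exactly
    expect_equal(mx[["d_nxy"]], 2 * d * b$bx * b$by)
    # replacing a record with itself changes nothing
    x <- runif(d, -b$bx, b$bx); y <- runif(1, -b$by, b$by)
    ui <- privlr:::upper_index(d)
    expect_equal(sum(abs((tcrossprod(x) - tcrossprod(x))[ui])), 0)
  })
})

test_that("released nyy satisfies the epsilon bound on adjacent data", {
  # adjacent one-record datasets at the extremes of the target bound;
  # empirical log-probability ratio of the discretized release must stay
  # below p3 * epsilon plus discretization/Monte-Carlo slack
  privlr:::with_seed(77, {
    eps3 <- 1
    by <- 1
    s <- by^2 / eps3
    n_draws <- 1e5
    r1 <- by^2 + rlaplace(n_draws, s)   # dataset with y = By
    r2 <- 0 + rlaplace(n_draws, s)      # neighbor with y = 0
    breaks <- seq(-6, 7, by = 0.5)
    c1 <- table(cut(pmin(pmax(r1, -5.9), 6.9), breaks))
    c2 <- table(cut(pmin(pmax(r2, -5.9), 6.9), breaks))
    keep <- c1 >= 500 & c2 >= 500
    ratio <- abs(log(as.numeric(c1[keep]) / as.numeric(c2[keep])))
    expect_lt(max(ratio), eps3 + 0.3)
  })
})

test_that("releases are self-describing, round-trip exactly, and refuse reuse", {
  reset_release_registry()
  d <- preprocess(random_dataset(40, 3, seed = 21))$data
  rel <- dp_release(d, threshold_spec(0.5, 0.5),
                    privacy_budget(2, c(0.35, 0.6, 0.05)), seed = 99)
  expect_true(rel$stats$is_noisy)
  expect_equal(rel$budget$p1 + rel$budget$p2 + rel$budget$p3, 1)

  path <- tempfile(fileext = ".json")
  write_release(rel, path)
  back <- read_release(path)
  expect_identical(back$stats$nxx, rel$stats$nxx)
  expect_identical(back$stats$nxy, rel$stats$nxy)
  expect_identical(back$stats$nyy, rel$stats$nyy)
  expect_equal(back$bounds$bx, rel$bounds$bx)
  expect_equal(back$seed, rel$seed)

  # double-spend guard: same data, same seed stream
  expect_error(dp_release(d, threshold_spec(0.5, 0.5),
                          privacy_budget(2, c(0.35, 0.6, 0.05)), seed = 99),
               "already exists")
  # different seed is a new (budget-consuming) release and is allowed
  rel2 <- dp_release(d, threshold_spec(0.5, 0.5),
                     privacy_budget(2, c(0.35, 0.6, 0.05)), seed = 100)
  expect_false(identical(rel2$stats$nxx, rel$stats$nxx))
  reset_release_registry()
})
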