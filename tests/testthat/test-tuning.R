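test_that("budget-split enumeration covers the constrained grid", {
  sp <- enumerate_budget_splits()
  expect_true(all(abs(rowSums(sp) - 1) < 1e-12))
  expect_true(all(sp >= 0.05 - 1e-12 & sp <= 0.90 + 1e-12))
  expect_true(any(abs(sp[, 1] - 0.35) < 1e-12 &
                  abs(sp[, 2] - 0.60) < 1e-12 &
                  abs(sp[, 3] - 0.05) < 1e-12))
  # lexicographic order
  expect_true(all(diff(sp[, 1] * 1e4 + sp[, 2]) > 0))
})

test_that("threshold-pair enumeration spans the multiplier grid", {
  pr <- enumerate_threshold_pairs()
  expect_equal(unname(pr[1, ]), c(0.1, 0.1))
  expect_equal(unname(pr[nrow(pr), ]), c(2.0, 2.0))
  expect_true(all(pr >= 0.1 & pr <= 2.0))
})

test_that("compiled and reference scorers agree exactly", {
  ds <- lapply(1:2, function(a) generate_auxiliary(60, 3, seed = a)$data)
  sp <- rbind(c(0.35, 0.60, 0.05), c(0.1, 0.1, 0.8))
  pr <- rbind(c(0.3, 0.3), c(1.0, 0.5))
  a <- privlr:::with_seed(4, privlr:::score_grid(ds, sp, pr, 2, n_noise = 3,
                                                 engine = "cpp"))
  b <- privlr:::with_seed(4, privlr:::score_grid(ds, sp, pr, 2, n_noise = 3,
                                                 engine = "r"))
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("candidate scores are deterministic and collapse in the noiseless limit", {
  ds <- lapply(1:2, function(a) generate_auxiliary(100, 4, seed = 10 + a)$data)
  s1 <- score_candidate(c(0.35, 0.6, 0.05), c(0.5, 0.5), ds, epsilon = 2,
                        n_noise = 3, seed = 5)
  s2 <- score_candidate(c(0.35, 0.6, 0.05), c(0.5, 0.5), ds, epsilon = 2,
                        n_noise = 3, seed = 5)
  expect_identical(s1, s2)

  # epsilon -> infinity: the split no longer matters
  splits <- rbind(c(0.05, 0.90, 0.05), c(0.90, 0.05, 0.05), c(1, 1, 1) / 3)
  scores <- sapply(seq_len(nrow(splits)), function(i) {
    score_candidate(splits[i, ], c(1, 1), ds, epsilon = 1e6, n_noise = 2,
                    seed = 6)
  })
  expect_lt(max(scores) - min(scores), 0.01)

  # degenerate average: 1 dataset x 1 draw equals the single evaluation
  one <- score_candidate(c(0.35, 0.6, 0.05), c(0.5, 0.5), ds[1], epsilon = 2,
                         n_noise = 1, seed = 7)
  expect_equal(length(one), 1L)
})

test_that("tiny tuning searches return grid members deterministically", {
  sp <- rbind(c(0.35, 0.60, 0.05), c(0.60, 0.35, 0.05))
  pr <- rbind(c(0.3, 0.3), c(0.8, 0.8))
  r1 <- tune_budget_split(n_aux = 80, d = 3, epsilon = 2, n_datasets = 2,
                          n_noise = 2, seed = 3, splits = sp, pairs = pr)
  r2 <- tune_budget_split(n_aux = 80, d = 3, epsilon = 2, n_datasets = 2,
                          n_noise = 2, seed = 3, splits = sp, pairs = pr)
  expect_identical(r1$best_split, r2$best_split)
  expect_identical(r1$table$score, r2$table$score)
  expect_true(any(apply(sp, 1, function(s) all(s == r1$best_split))))

  # single-candidate grid returns that candidate
  r3 <- tune_budget_split(n_aux = 50, d = 3, epsilon = 2, n_datasets = 1,
                          n_noise = 1, seed = 1,
                          splits = matrix(c(0.2, 0.7, 0.1), 1),
                          pairs = matrix(c(0.5, 0.5), 1))
  expect_equal(r3$best_split, c(0.2, 0.7, 0.1))

  rt <- tune_thresholds(c(0.35, 0.6, 0.05), n_aux = 80, d = 3, epsilon = 2,
                        n_datasets = 2, n_noise = 2, seed = 4, pairs = pr)
  expect_true(any(apply(pr, 1, function(p) all(p == rt$best_omegas))))
})

test_that("tuning results serialize to JSON and CSV", {
  r <- tune_budget_split(n_aux = 50, d = 3, epsilon = 2, n_datasets = 1,
                         n_noise = 1, seed = 1,
                         splits = rbind(c(0.2, 0.7, 0.1), c(0.7, 0.2, 0.1)),
                         pairs = matrix(c(0.5, 0.5), 1))
  jp <- tempfile(fileext = ".json")
  cp <- tempfile(fileext = ".csv")
  write_tuning_result(r, jp, cp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(as.numeric(back$best_split), r$best_split)
  tab <- read.csv(cp)
  expect_equal(nrow(tab), 2L)
})
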