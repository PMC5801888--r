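# Grid searches on auxiliary synthetic data: privacy-budget split first,
# then projection-threshold multipliers. All tuning fits use the
# fixed-precision conjugate path with lambda = lambda0 = 1, which makes the
# 171 x 400 joint sweep tractable.

#' Enumerate candidate privacy-budget splits
#'
#' All triples `(p1, p2, p3)` on the `step` grid with every share in
#' `[min_share, max_share]` and summing exactly to 1, in lexicographic order.
#' With the defaults (step 0.05, shares in `[0.05, 0.90]`) there are 171
#' candidates.
#'
#' @param step grid step (default 0.05).
#' @param min_share,max_share share range.
#' @return Numeric matrix with columns `p1`, `p2`, `p3`.
#' @export
enumerate_budget_splits <- function(step = 0.05, min_share = 0.05,
                                    max_share = 0.90) {
  units <- round(1 / step)
  lo <- round(min_share / step)
  hi <- round(max_share / step)
  out <- list()
  for (i in lo:hi) for (j in lo:hi) {
    k <- units - i - j
    if (k >= lo && k <= hi) out[[length(out) + 1]] <- c(i, j, k)
  }
  m <- do.call(rbind, out) * step
  colnames(m) <- c("p1", "p2", "p3")
  m
}

#' Enumerate candidate projection-threshold multiplier pairs
#'
#' The Cartesian product of the multiplier grid `{0.1, 0.2, ..., 2.0}` with
#' itself (400 pairs), lexicographic in `(omega_x, omega_y)`.
#'
#' @param omega_grid multiplier grid for both axes.
#' @return Numeric matrix with columns `omega_x`, `omega_y`.
#' @export
enumerate_threshold_pairs <- function(omega_grid = seq(0.1, 2.0, by = 0.1)) {
  m <- as.matrix(expand.grid(omega_y = omega_grid, omega_x = omega_grid))
  m <- m[, c("omega_x", "omega_y")]
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# R reference scorer mirroring cpp_score_block exactly (same unit noise,
# same PSD repair, same posterior); kept as the cross-check oracle for the
# compiled path
score_block_r <- function(nxx, nxy, Xproj, rank_y, scales, Exx, Exy,
                          lambda = 1, lambda0 = 1, repair = TRUE) {
  d <- length(nxy)
  ui <- upper_index(d)
  S <- nrow(scales)
  K <- nrow(Exx)
  out <- matrix(NA_real_, S, K)
  for (s in seq_len(S)) {
    for (k in seq_len(K)) {
      A <- nxx
      A[ui] <- A[ui] + scales[s, 1] * Exx[k, ]
      A[lower.tri(A)] <- t(A)[lower.tri(A)]
      if (repair && scales[s, 1] != 0) A <- psd_repair(A)
      Lam <- lambda0 * diag(d) + lambda * A
      mu <- solve(Lam, lambda * (nxy + scales[s, 2] * Exy[k, ]))
      yhat <- as.numeric(Xproj %*% mu)
      if (sd(yhat) == 0) {
        out[s, k] <- -1
      } else {
        out[s, k] <- cor(rank(yhat), rank_y)
      }
    }
  }
  out
}

# Shared engine of all sweeps. datasets: list of labeled_dataset (auxiliary);
# splits: S x 3; pairs: P x 2 (omega_x, omega_y); returns S x P mean
# Spearman over datasets x n_noise draws. Noise uses common random numbers:
# per (dataset, draw) one set of unit Laplace variates is scaled by each
# candidate's scales, mirroring a fixed set of "generated noise samples"
# reused across candidates.
score_grid <- function(datasets, splits, pairs, epsilon, n_noise,
                       lambda = 1, lambda0 = 1, private = TRUE,
                       repair = TRUE, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  splits <- matrix(splits, ncol = 3)
  pairs <- matrix(pairs, ncol = 2)
  S <- nrow(splits)
  P <- nrow(pairs)
  acc <- matrix(0, S, P)
  for (a in seq_along(datasets)) {
    data <- datasets[[a]]
    d <- data$d
    nu <- d * (d + 1) / 2
    sig <- estimate_sigmas(data)
    rank_y <- rank(data$y)
    if (private) {
      Exx <- matrix(rlaplace(n_noise * nu), n_noise, nu)
      Exy <- matrix(rlaplace(n_noise * d), n_noise, d)
    } else {
      Exx <- matrix(0, 1, nu)
      Exy <- matrix(0, 1, d)
    }
    for (p in seq_len(P)) {
      b <- bounds(pairs[p, 1] * sig[["sigma_x"]],
                  pairs[p, 2] * sig[["sigma_y"]])
      proj <- project_dataset(data, b)
      st <- sufficient_stats(proj)
      scales <- if (private) {
        t(vapply(seq_len(S), function(s) {
          sc <- laplace_scales(d, b, privacy_budget(epsilon, splits[s, ]))
          c(sc$s_xx, sc$s_xy)
        }, numeric(2)))
      } else {
        matrix(0, S, 2)
      }
      block <- if (engine == "cpp") {
        cpp_score_block(st$nxx, st$nxy, proj$X, rank_y, scales, Exx, Exy,
                        lambda, lambda0, repair)
      } else {
        score_block_r(st$nxx, st$nxy, proj$X, rank_y, scales, Exx, Exy,
                      lambda, lambda0, repair)
      }
      acc[, p] <- acc[, p] + rowMeans(block)
    }
  }
  acc / length(datasets)
}

make_aux_datasets <- function(n_datasets, n_aux, d, lambda, lambda0, seed,
                              tail = "gaussian") {
  lapply(seq_len(n_datasets), function(a) {
    generate_auxiliary(n_aux, d, lambda, lambda0, tail = tail,
                       seed = spawn_seed(seed, paste0("aux", a)))$data
  })
}

#' Score one (budget split, threshold pair) candidate on auxiliary data
#'
#' For each auxiliary dataset and each noise draw: estimate the sigmas, form
#' bounds from the multipliers, project, compute the statistics, perturb
#' them at the candidate split, fit the fixed-precision posterior
#' (`lambda = lambda0 = 1`), predict on the (projected) auxiliary inputs and
#' Spearman-correlate against the original, unprojected targets. Returns the
#' mean over datasets x draws. A degenerate constant prediction scores -1
#' (with a warning): the rank correlation is undefined there and -1 removes
#' the candidate from contention.
#'
#' @param split numeric `c(p1, p2, p3)`.
#' @param omegas numeric `c(omega_x, omega_y)`.
#' @param datasets list of auxiliary [labeled_dataset()]s.
#' @param epsilon total privacy budget.
#' @param n_noise noise draws per dataset.
#' @param seed optional seed for the noise draws.
#' @param private `FALSE` scores the noiseless (non-private) analogue.
#' @return Mean Spearman score (scalar).
#' @export
score_candidate <- function(split, omegas, datasets, epsilon, n_noise = 5,
                            seed = NULL, private = TRUE) {
  sc <- with_seed(seed,
    score_grid(datasets, matrix(split, 1), matrix(omegas, 1),
               epsilon, n_noise, private = private))
  if (any(sc == -1)) warning("degenerate constant predictions scored as -1")
  as.numeric(sc)
}

new_tuning_result <- function(best_split, best_omegas, table, depths, seed) {
  structure(list(best_split = best_split, best_omegas = best_omegas,
                 table = table, depths = depths, seed = seed),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> best split = (%g, %g, %g), best omegas = (%g, %g)\n",
              x$best_split[1], x$best_split[2], x$best_split[3],
              x$best_omegas[1], x$best_omegas[2]))
  cat(sprintf("  averaged over %d datasets x %d noise draws\n",
              x$depths[1], x$depths[2]))
  invisible(x)
}

#' Tune the privacy-budget split on auxiliary synthetic data
#'
#' Exhaustive search over all splits on the 0.05 grid. For every split the
#' best projection-threshold pair is chosen jointly from the 400-pair grid,
#' and the split is scored by that best pair's mean Spearman over
#' `n_datasets` auxiliary datasets times `n_noise` noise draws (default
#' 5 x 5). Ties break to the lexicographically smallest candidate.
#'
#' @param n_aux auxiliary dataset size (default 500).
#' @param d dimensionality (default 10).
#' @param epsilon total privacy budget (default 2).
#' @param n_datasets,n_noise averaging depths.
#' @param seed master seed.
#' @param splits,pairs candidate grids (defaults: the full grids).
#' @param lambda,lambda0 fixed precisions for the tuning fits.
#' @return A `tuning_result`; `table` holds one row per split with its best
#'   pair and score.
#' @export
tune_budget_split <- function(n_aux = 500, d = 10, epsilon = 2,
                              n_datasets = 5, n_noise = 5, seed = 1,
                              splits = enumerate_budget_splits(),
                              pairs = enumerate_threshold_pairs(),
                              lambda = 1, lambda0 = 1) {
  datasets <- make_aux_datasets(n_datasets, n_aux, d, lambda, lambda0, seed)
  sc <- with_seed(spawn_seed(seed, "noise"),
                  score_grid(datasets, splits, pairs, epsilon, n_noise,
                             lambda, lambda0))
  best_p <- apply(sc, 1, which.max)
  best_score <- sc[cbind(seq_len(nrow(sc)), best_p)]
  win <- which.max(best_score)
  table <- data.frame(splits,
                      omega_x = pairs[best_p, 1], omega_y = pairs[best_p, 2],
                      score = best_score)
  new_tuning_result(unname(splits[win, ]), unname(pairs[best_p[win], ]),
                    table, c(n_datasets, n_noise), seed)
}

#' Tune the projection thresholds at a fixed budget split
#'
#' Scores all 400 multiplier pairs at the given split, averaging over
#' `n_datasets` x `n_noise` (default 20 x 20 for the final selection).
#'
#' @param split numeric `c(p1, p2, p3)` (typically the tuned optimum).
#' @inheritParams tune_budget_split
#' @param private `FALSE` runs the noiseless analogue of the sweep.
#' @return A `tuning_result`; `table` holds one row per pair.
#' @export
tune_thresholds <- function(split, n_aux = 500, d = 10, epsilon = 2,
                            n_datasets = 20, n_noise = 20, seed = 1,
                            pairs = enumerate_threshold_pairs(),
                            lambda = 1, lambda0 = 1, private = TRUE) {
  datasets <- make_aux_datasets(n_datasets, n_aux, d, lambda, lambda0, seed)
  sc <- with_seed(spawn_seed(seed, "noise"),
                  score_grid(datasets, matrix(split, 1), pairs, epsilon,
                             n_noise, lambda, lambda0, private = private))
  win <- which.max(sc[1, ])
  table <- data.frame(pairs, score = sc[1, ])
  new_tuning_result(split, unname(pairs[win, ]), table,
                    c(n_datasets, n_noise), seed)
}

#' Sweep a single projection-threshold multiplier across sample sizes
#'
#' The bounding experiment: for each sample size, sweep a common multiplier
#' `omega = omega_x = omega_y` over the grid, scoring each value by mean
#' Spearman over `n_reps` independent auxiliary datasets (one noise draw
#' each), either privately at the given split and epsilon or noiselessly.
#'
#' @param ns sample sizes to test.
#' @param split budget split for the private runs.
#' @param epsilon total budget.
#' @param omegas multiplier grid.
#' @param n_reps repetitions per point.
#' @param d dimensionality.
#' @param seed master seed.
#' @param private `FALSE` for the non-private reference sweep.
#' @param lambda,lambda0 fixed precisions.
#' @return Data frame with columns `n`, `omega`, `score`, plus attribute
#'   `argmax` (data frame of the best omega per sample size).
#' @export
sweep_projection_threshold <- function(ns = c(250, 500, 1000),
                                       split = c(0.35, 0.60, 0.05),
                                       epsilon = 2,
                                       omegas = seq(0.1, 2.0, by = 0.1),
                                       n_reps = 20, d = 10, seed = 1,
                                       private = TRUE,
                                       lambda = 1, lambda0 = 1) {
  pairs <- cbind(omegas, omegas)
  res <- lapply(ns, function(n) {
    datasets <- make_aux_datasets(n_reps, n, d, lambda, lambda0,
                                  spawn_seed(seed, paste0("n", n)))
    sc <- with_seed(spawn_seed(seed, paste0("noise", n)),
                    score_grid(datasets, matrix(split, 1), pairs, epsilon,
                               n_noise = 1, lambda, lambda0,
                               private = private))
    data.frame(n = n, omega = omegas, score = sc[1, ])
  })
  out <- do.call(rbind, res)
  argmax <- do.call(rbind, lapply(base::split(out, out$n), function(df) {
    data.frame(n = df$n[1], omega = df$omega[which.max(df$score)],
               score = max(df$score))
  }))
  rownames(argmax) <- NULL
  attr(out, "argmax") <- argmax
  out
}

#' Serialize a tuning result to JSON (and optionally its score table to CSV)
#'
#' @param result a `tuning_result`.
#' @param path JSON output path.
#' @param table_path optional CSV path for the full score table.
#' @return Invisibly, `path`.
#' @export
write_tuning_result <- function(result, path, table_path = NULL) {
  stopifnot(inherits(result, "tuning_result"))
  payload <- list(format = "privlr_tuning",
                  best_split = result$best_split,
                  best_omegas = result$best_omegas,
                  depths = result$depths, seed = result$seed)
  write_json_full(payload, path)
  if (!is.null(table_path)) {
    write.table(result$table, table_path, sep = ",", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
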