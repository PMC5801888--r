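# Metrics and the Monte Carlo cross-validation experiment driver.

#' Spearman rank correlation
#'
#' Pearson correlation of the average-rank vectors; ties get average ranks.
#' A constant vector has undefined rank correlation and is an error — the
#' caller decides the fallback (the experiment driver records such scores as
#' missing).
#'
#' @param y_true,y_pred numeric vectors of equal length `>= 2`.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_cor <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  if (sd(y_true) == 0 || sd(y_pred) == 0) {
    stop("Spearman correlation undefined for a constant vector")
  }
  cor(rank(y_true), rank(y_pred))
}

#' Random train/test/non-private partition for Monte Carlo cross-validation
#'
#' Splits `1:n_total` into disjoint test, non-private and private index
#' sets; the private set is the remainder.
#'
#' @param n_total total sample count.
#' @param n_test test set size.
#' @param n_nonprivate non-private (internal) training set size.
#' @param seed optional seed.
#' @return List with integer vectors `test`, `nonprivate`, `private`.
#' @export
mc_partition <- function(n_total, n_test, n_nonprivate, seed = NULL) {
  if (n_test + n_nonprivate > n_total) {
    stop("infeasible partition: n_test + n_nonprivate > n_total")
  }
  with_seed(seed, {
    perm <- sample.int(n_total)
    list(test = sort(perm[seq_len(n_test)]),
         nonprivate = sort(perm[n_test + seq_len(n_nonprivate)]),
         private = sort(perm[-seq_len(n_test + n_nonprivate)]))
  })
}

subset_dataset <- function(data, idx, private = TRUE) {
  labeled_dataset(data$X[idx, , drop = FALSE], data$y[idx], private = private)
}

#' Configuration for the cross-validation experiment
#'
#' @param n_repeats Monte Carlo repeats (default 50).
#' @param n_test test set size per repeat (default 100).
#' @param n_nonprivate non-private training points (default 30).
#' @param n_private private training set sizes to test.
#' @param epsilons privacy budgets to test.
#' @param split budget split for the private method.
#' @param omegas threshold multipliers `c(omega_x, omega_y)`.
#' @param mode `"fixed"` or `"hierarchical"` inference.
#' @param m posterior draws in hierarchical mode.
#' @param project_test clip test inputs with the training bounds (default
#'   `TRUE`).
#' @param private_noproj also run the private method without projection
#'   (bounds from the data maximum, nothing clipped).
#' @param nonprivate_robust also run the projected non-private variant.
#' @param seed master seed.
#' @return Named list of class `experiment_config`.
#' @export
experiment_config <- function(n_repeats = 50, n_test = 100, n_nonprivate = 30,
                              n_private = c(100, 200, 400, 800),
                              epsilons = 2,
                              split = c(0.35, 0.60, 0.05),
                              omegas = c(0.4, 0.4),
                              mode = c("fixed", "hierarchical"), m = 5000,
                              project_test = TRUE, private_noproj = FALSE,
                              nonprivate_robust = FALSE, seed = 1) {
  mode <- match.arg(mode)
  structure(list(n_repeats = n_repeats, n_test = n_test,
                 n_nonprivate = n_nonprivate, n_private = n_private,
                 epsilons = epsilons, split = split, omegas = omegas,
                 mode = mode, m = m, project_test = project_test,
                 private_noproj = private_noproj,
                 nonprivate_robust = nonprivate_robust, seed = seed),
            class = "experiment_config")
}

fit_stats <- function(stats, config, seed = NULL) {
  if (config$mode == "fixed") {
    posterior_fixed(stats, 1, 1)
  } else {
    fit_hierarchical(stats, prior_spec("hierarchical"), m = config$m,
                     seed = seed)
  }
}

#' Run the Monte Carlo cross-validation experiment
#'
#' For each repeat and task (e.g. drug): preprocess the task's data;
#' partition into test / non-private / private; estimate the clipping sigmas
#' on the private part; project private and non-private training data with
#' the same bounds; compute, perturb (at each epsilon) and combine the
#' statistics; fit; predict on the test inputs; score by Spearman. Alongside
#' the private method it runs the non-private comparator (same pipeline, no
#' noise, no projection) and the baseline that uses only the non-private
#' subset. Constant predictions give a missing score (excluded from means
#' downstream), with a count carried in the `n_degenerate` attribute.
#'
#' @param tasks a single [labeled_dataset()] or a named list of them.
#' @param config an [experiment_config()].
#' @return Tidy data frame: one row per repeat x task x method x setting
#'   with columns `repeat_id`, `task`, `method`, `n_private`,
#'   `n_nonprivate`, `epsilon`, `spearman`, `seed`.
#' @export
run_experiment <- function(tasks, config = experiment_config()) {
  if (inherits(tasks, "labeled_dataset")) tasks <- list(task = tasks)
  rows <- list()
  n_degenerate <- 0L
  add_row <- function(rep_id, task, method, np, eps, score, seed) {
    rows[[length(rows) + 1L]] <<- data.frame(
      repeat_id = rep_id, task = task, method = method, n_private = np,
      n_nonprivate = config$n_nonprivate, epsilon = eps,
      spearman = score, seed = seed)
  }
  safe_spearman <- function(y, yhat) {
    if (sd(yhat) == 0) {
      n_degenerate <<- n_degenerate + 1L
      return(NA_real_)
    }
    spearman_cor(y, yhat)
  }
  for (r in seq_len(config$n_repeats)) {
    rep_seed <- spawn_seed(config$seed, paste0("repeat", r))
    for (task_name in names(tasks)) {
      task <- tasks[[task_name]]
      if (task$n < config$n_test + config$n_nonprivate + 2) {
        message("skipping task ", task_name, " in repeat ", r,
                ": too few usable samples (", task$n, ")")
        next
      }
      pp <- preprocess(task)
      data <- pp$data
      part <- mc_partition(data$n, config$n_test, config$n_nonprivate,
                           seed = spawn_seed(rep_seed, task_name))
      test <- subset_dataset(data, part$test)
      nonpriv <- subset_dataset(data, part$nonprivate, private = FALSE)
      if (test$n < 2) {
        message("skipping task ", task_name, " in repeat ", r,
                ": < 2 usable test points")
        next
      }
      # baseline: non-private subset only, no projection, no noise
      if (nonpriv$n >= 1) {
        fit_b <- fit_stats(sufficient_stats(nonpriv), config,
                           seed = spawn_seed(rep_seed, "fit_base"))
        add_row(r, task_name, "baseline", 0L, NA_real_,
                safe_spearman(test$y, predict(fit_b, test$X)), config$seed)
      }
      for (np in config$n_private) {
        if (np > length(part$private)) {
          message("skipping n_private = ", np, " for task ", task_name,
                  ": only ", length(part$private), " private samples")
          next
        }
        if (np == 0) {
          # no private statistics contributed: the private method reduces
          # exactly to the non-private-subset baseline
          fit0 <- fit_stats(sufficient_stats(nonpriv), config,
                            seed = spawn_seed(rep_seed, "fit_base"))
          s0 <- safe_spearman(test$y, predict(fit0, test$X))
          add_row(r, task_name, "nonprivate", 0L, NA_real_, s0, config$seed)
          for (eps in config$epsilons) {
            add_row(r, task_name, "robust_private", 0L, eps, s0, config$seed)
          }
          next
        }
        priv <- subset_dataset(data, part$private[seq_len(np)])
        # non-private comparator: all training data, clean, unprojected
        train_clean <- combine_stats(sufficient_stats(priv),
                                     sufficient_stats(nonpriv))
        fit_np <- fit_stats(train_clean, config,
                            seed = spawn_seed(rep_seed, "fit_np"))
        add_row(r, task_name, "nonprivate", np, NA_real_,
                safe_spearman(test$y, predict(fit_np, test$X)), config$seed)
        if (np == 0) next
        sig <- estimate_sigmas(priv)
        b <- bounds(config$omegas[1] * sig[["sigma_x"]],
                    config$omegas[2] * sig[["sigma_y"]])
        priv_proj <- project_dataset(priv, b)
        nonpriv_proj <- project_dataset(nonpriv, b)
        test_X <- if (config$project_test) clip_values(test$X, b$bx) else test$X
        if (config$nonprivate_robust) {
          st_r <- combine_stats(sufficient_stats(priv_proj),
                                sufficient_stats(nonpriv_proj))
          fit_r <- fit_stats(st_r, config,
                             seed = spawn_seed(rep_seed, "fit_r"))
          add_row(r, task_name, "nonprivate_robust", np, NA_real_,
                  safe_spearman(test$y, predict(fit_r, test_X)), config$seed)
        }
        for (eps in config$epsilons) {
          budget <- privacy_budget(eps, config$split)
          noisy <- with_seed(
            spawn_seed(rep_seed, paste0("noise", np, "e", eps)),
            perturb_stats(sufficient_stats(priv_proj),
                          laplace_scales(data$d, b, budget)))
          st_p <- combine_stats(noisy, sufficient_stats(nonpriv_proj))
          fit_p <- fit_stats(st_p, config,
                             seed = spawn_seed(rep_seed, "fit_p"))
          add_row(r, task_name, "robust_private", np, eps,
                  safe_spearman(test$y, predict(fit_p, test_X)), config$seed)
          if (config$private_noproj) {
            bmax <- bounds(max(abs(priv$X)), max(abs(priv$y)))
            noisy2 <- with_seed(
              spawn_seed(rep_seed, paste0("noise2_", np, "e", eps)),
              perturb_stats(sufficient_stats(priv),
                            laplace_scales(data$d, bmax, budget)))
            st_p2 <- combine_stats(noisy2, sufficient_stats(nonpriv))
            fit_p2 <- fit_stats(st_p2, config,
                                seed = spawn_seed(rep_seed, "fit_p2"))
            add_row(r, task_name, "private_noproj", np, eps,
                    safe_spearman(test$y, predict(fit_p2, test$X)),
                    config$seed)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_degenerate") <- n_degenerate
  out
}

#' Summarize experiment results over repeats
#'
#' Mean and standard deviation of the Spearman score per (task-averaged)
#' method and setting, matching the convention of reporting error bars as
#' the standard deviation over Monte Carlo repeats. Missing scores
#' (degenerate predictions) are excluded, with their count reported.
#'
#' @param results data frame from [run_experiment()].
#' @return Data frame with columns `method`, `n_private`, `epsilon`,
#'   `mean_spearman`, `sd_spearman`, `n_repeats`, `n_missing`.
#' @export
summarize_experiment <- function(results) {
  eps_key <- ifelse(is.na(results$epsilon), -1, results$epsilon)
  key <- interaction(results$method, results$n_private, eps_key, drop = TRUE)
  out <- do.call(rbind, lapply(base::split(results, key), function(df) {
    per_rep <- tapply(df$spearman, df$repeat_id,
                      function(v) mean(v, na.rm = TRUE))
    data.frame(method = df$method[1], n_private = df$n_private[1],
               epsilon = df$epsilon[1],
               mean_spearman = mean(per_rep, na.rm = TRUE),
               sd_spearman = sd(per_rep, na.rm = TRUE),
               n_repeats = length(per_rep),
               n_missing = sum(is.na(df$spearman)))
  }))
  rownames(out) <- NULL
  out[order(out$method, out$n_private), ]
}

#' Tune the projection threshold for a sample size on auxiliary data
#'
#' Mirrors the practice of choosing the clipping threshold per test case:
#' sweep a common multiplier on auxiliary synthetic datasets of the target
#' size and return the in-sample argmax.
#'
#' @param n private training set size the threshold is tuned for.
#' @param d dimensionality.
#' @param epsilon total budget.
#' @param split budget split.
#' @param n_reps auxiliary datasets averaged per grid point.
#' @param seed seed for the auxiliary data and noise.
#' @param omegas multiplier grid.
#' @return The winning multiplier (scalar).
#' @export
tune_omega_for_n <- function(n, d = 10, epsilon = 2,
                             split = c(0.35, 0.60, 0.05), n_reps = 5,
                             seed = 1, omegas = seq(0.1, 2.0, by = 0.1)) {
  sw <- sweep_projection_threshold(ns = n, split = split, epsilon = epsilon,
                                   omegas = omegas, n_reps = n_reps, d = d,
                                   seed = seed)
  attr(sw, "argmax")$omega[1]
}

#' Test-set accuracy gap between private and non-private fits
#'
#' The asymptotic-efficiency probe: draw a training set of size `n` and a
#' test set from the same coefficients, fit the non-private model (clean
#' statistics, no projection) and the robust private model (projection at
#' `omega` standard deviations, Laplace noise at `epsilon` with the given
#' split), and return the Spearman scores of both on the test set, averaged
#' over `n_seeds` replicate worlds.
#'
#' @param n training set size.
#' @param omega common clipping multiplier for the private fit.
#' @param d dimensionality.
#' @param epsilon total budget.
#' @param split budget split.
#' @param n_seeds number of replicate worlds averaged.
#' @param seed base seed.
#' @param n_test test set size.
#' @return Named vector `c(nonprivate, private, gap)` of means.
#' @export
efficiency_gap <- function(n, omega, d = 10, epsilon = 2,
                           split = c(0.35, 0.60, 0.05), n_seeds = 20,
                           seed = 1, n_test = 1000) {
  one <- function(s) {
    g <- generate_auxiliary(n + n_test, d, seed = spawn_seed(s, "world"))
    tr <- labeled_dataset(g$data$X[seq_len(n), , drop = FALSE],
                          g$data$y[seq_len(n)])
    te_idx <- n + seq_len(n_test)
    te <- labeled_dataset(g$data$X[te_idx, , drop = FALSE], g$data$y[te_idx])
    f0 <- posterior_fixed(sufficient_stats(tr), 1, 1)
    s0 <- spearman_cor(te$y, predict(f0, te$X))
    sig <- estimate_sigmas(tr)
    b <- bounds(omega * sig[["sigma_x"]], omega * sig[["sigma_y"]])
    noisy <- with_seed(spawn_seed(s, "noise"),
      perturb_stats(sufficient_stats(project_dataset(tr, b)),
                    laplace_scales(d, b, privacy_budget(epsilon, split))))
    f1 <- posterior_fixed(noisy, 1, 1)
    s1 <- spearman_cor(te$y, predict(f1, clip_values(te$X, b$bx)))
    c(s0, s1)
  }
  m <- rowMeans(vapply(seed + seq_len(n_seeds), one, numeric(2)))
  c(nonprivate = m[1], private = m[2], gap = m[1] - m[2])
}
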