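# The Laplace mechanism on the three sufficient statistics: budget split,
# noise scales, perturbation, an empirical sensitivity oracle, and the
# self-describing release artifact.

#' Privacy budget with a three-way split
#'
#' The total budget epsilon is split as `p1 + p2 + p3 = 1` across the three
#' released statistics (`nxx`, `nxy`, `nyy`); by the composition theorem the
#' three independent Laplace mechanisms with budgets `p_i * epsilon` together
#' give an epsilon-differentially-private release.
#'
#' @param epsilon positive total privacy budget.
#' @param split numeric vector `c(p1, p2, p3)`, all positive, summing to 1
#'   within `1e-9`.
#' @return Object of class `privacy_budget`.
#' @export
privacy_budget <- function(epsilon, split = c(0.35, 0.60, 0.05)) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1, length(split) == 3)
  if (!(epsilon > 0)) stop("epsilon must be strictly positive")
  if (any(split <= 0)) stop("all budget shares must be strictly positive")
  if (abs(sum(split) - 1) > 1e-9) {
    stop("budget shares must sum to 1 (got ", format(sum(split), digits = 12), ")")
  }
  structure(list(epsilon = epsilon, p1 = split[1], p2 = split[2], p3 = split[3]),
            class = "privacy_budget")
}

#' @export
print.privacy_budget <- function(x, ...) {
  cat(sprintf("<privacy_budget> epsilon = %g, split = (%g, %g, %g)\n",
              x$epsilon, x$p1, x$p2, x$p3))
  invisible(x)
}

#' Laplace noise scales for the three sufficient statistics
#'
#' For data clipped to `[-Bx, Bx]` and `[-By, By]`, replacing one record
#' changes the `d(d+1)/2` unique entries of `nxx` by at most `(d^2+d) Bx^2`
#' in L1, `nxy` by at most `2 d Bx By`, and `nyy` by at most `By^2`. The
#' Laplace scales are these sensitivities divided by the per-statistic
#' budgets:
#' `s_xx = (d^2+d) Bx^2 / (p1 eps)`, `s_xy = 2 d Bx By / (p2 eps)`,
#' `s_yy = By^2 / (p3 eps)`.
#'
#' @param d dimensionality of the inputs.
#' @param b a [bounds()] object.
#' @param budget a [privacy_budget()].
#' @return Object of class `noise_scales` with fields `s_xx`, `s_xy`, `s_yy`.
#' @export
laplace_scales <- function(d, b, budget) {
  stopifnot(inherits(b, "bounds"), inherits(budget, "privacy_budget"),
            d >= 1, d == as.integer(d))
  eps <- budget$epsilon
  structure(list(
    s_xx = (d^2 + d) * b$bx^2 / (budget$p1 * eps),
    s_xy = 2 * d * b$bx * b$by / (budget$p2 * eps),
    s_yy = b$by^2 / (budget$p3 * eps),
    d = as.integer(d)
  ), class = "noise_scales")
}

#' Draw from the Laplace distribution
#'
#' Inverse-CDF sampler for `Laplace(0, scale)`; `scale = 0` returns exact
#' zeros (the noiseless limit).
#'
#' @param n number of draws.
#' @param scale nonnegative scale parameter (mean absolute deviation).
#' @return Numeric vector of draws.
#' @export
rlaplace <- function(n, scale = 1) {
  stopifnot(scale >= 0)
  u <- runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

# canonical ordering of the unique entries of a symmetric d x d matrix:
# column-major upper triangle including the diagonal
upper_index <- function(d) which(upper.tri(diag(d), diag = TRUE))

#' Perturb clean sufficient statistics with Laplace noise
#'
#' Independent Laplace noise is added to each of the `d(d+1)/2` unique
#' entries of `nxx` (then mirrored, so the release is exactly symmetric), to
#' each entry of `nxy`, and to `nyy`. The sample count is treated as public
#' and left unchanged. Perturbing an already-noisy object is refused: that
#' would be spending budget on a release twice.
#'
#' @param stats clean `suff_stats`.
#' @param scales a [laplace_scales()] object.
#' @param unit_noise optional list with pre-drawn unit-scale Laplace draws
#'   `exx` (length `d(d+1)/2`), `exy` (length `d`), `eyy` (length 1); used
#'   for common-random-number designs. Default: fresh draws from the current
#'   RNG stream.
#' @return Noisy `suff_stats` with `is_noisy = TRUE`.
#' @export
perturb_stats <- function(stats, scales, unit_noise = NULL) {
  stopifnot(inherits(stats, "suff_stats"), inherits(scales, "noise_scales"))
  if (stats$is_noisy) {
    stop("refusing to perturb already-noisy statistics (double budget spend)")
  }
  if (scales$d != stats$d) stop("noise scales were computed for d = ", scales$d,
                                ", statistics have d = ", stats$d)
  d <- stats$d
  nu <- d * (d + 1) / 2
  if (is.null(unit_noise)) {
    unit_noise <- list(exx = rlaplace(nu), exy = rlaplace(d), eyy = rlaplace(1))
  }
  stopifnot(length(unit_noise$exx) == nu, length(unit_noise$exy) == d)
  nxx <- stats$nxx
  nxx[upper_index(d)] <- nxx[upper_index(d)] + scales$s_xx * unit_noise$exx
  nxx[lower.tri(nxx)] <- t(nxx)[lower.tri(nxx)]
  new_suff_stats(
    nxx = nxx,
    nxy = stats$nxy + scales$s_xy * unit_noise$exy,
    nyy = stats$nyy + scales$s_yy * unit_noise$eyy[1],
    n = stats$n, is_noisy = TRUE
  )
}

#' Empirical sensitivity search for the three statistics
#'
#' Randomized oracle backing the noise calibration: draws random datasets
#' with all entries inside the bounds, replaces a single record with another
#' in-bounds record, and records the L1 change of the unique entries of
#' `nxx`, of `nxy`, and the absolute change of `nyy`. The maxima over all
#' trials must stay below the claimed sensitivities `(d^2+d) Bx^2`,
#' `2 d Bx By` and `By^2`.
#'
#' @param d dimensionality.
#' @param b a [bounds()] object.
#' @param n_trials number of random replacement trials.
#' @param include_adversarial also test the extremal pair that attains the
#'   `nxy` bound exactly (`x = Bx * 1, y = By` vs `x = -Bx * 1, y = By`).
#' @return Named vector `c(d_nxx, d_nxy, d_nyy)` of maximum observed changes.
#' @export
check_sensitivity <- function(d, b, n_trials = 1000, include_adversarial = TRUE) {
  stopifnot(n_trials >= 1, inherits(b, "bounds"))
  ui <- upper_index(d)
  one_change <- function(x, y, x2, y2) {
    dxx <- sum(abs((tcrossprod(x) - tcrossprod(x2))[ui]))
    c(dxx, sum(abs(x * y - x2 * y2)), abs(y^2 - y2^2))
  }
  draw <- function() list(x = runif(d, -b$bx, b$bx), y = runif(1, -b$by, b$by))
  mx <- c(0, 0, 0)
  for (i in seq_len(n_trials)) {
    r1 <- draw(); r2 <- draw()
    mx <- pmax(mx, one_change(r1$x, r1$y, r2$x, r2$y))
  }
  if (include_adversarial) {
    mx <- pmax(mx, one_change(rep(b$bx, d), b$by, rep(-b$bx, d), b$by))
    mx <- pmax(mx, one_change(rep(b$bx, d), b$by, rep(b$bx, d), -b$by))
  }
  c(d_nxx = mx[1], d_nxy = mx[2], d_nyy = mx[3])
}

# registry for the double-spend guard: (statistics fingerprint, seed) pairs
# already used to produce a release in this session
.release_registry <- new.env(parent = emptyenv())

#' Produce a differentially private release of a dataset
#'
#' End-to-end mechanism: materialize the clipping bounds from the threshold
#' spec (estimating sigmas from the data unless given), project the data,
#' compute the sufficient statistics, and perturb them with Laplace noise at
#' the given budget. The result is a self-describing artifact: together with
#' the public metadata it is all a modeller ever needs from the private data.
#'
#' Re-releasing the same statistics under the same named seed is refused —
#' the seeded noise would be identical, so the two artifacts would jointly
#' leak more than epsilon.
#'
#' @param data a preprocessed private [labeled_dataset()].
#' @param spec a [threshold_spec()]; sigmas are estimated from `data` if
#'   unset.
#' @param budget a [privacy_budget()].
#' @param seed integer seed naming this release's noise stream.
#' @return Object of class `private_release`.
#' @export
dp_release <- function(data, spec, budget, seed) {
  stopifnot(inherits(data, "labeled_dataset"), data$private,
            inherits(spec, "threshold_spec"), inherits(budget, "privacy_budget"),
            is.numeric(seed), length(seed) == 1)
  if (is.na(spec$sigma_x) || is.na(spec$sigma_y)) {
    spec <- do.call(threshold_spec, modifyList(unclass(spec),
                                               as.list(estimate_sigmas(data))))
  }
  b <- bounds_from_spec(spec)
  clean <- sufficient_stats(project_dataset(data, b))
  key <- paste(fingerprint(clean[c("nxx", "nxy", "nyy", "n")]), seed, sep = "@")
  if (exists(key, envir = .release_registry, inherits = FALSE)) {
    stop("a release of these statistics with seed ", seed,
         " already exists; reusing the noise stream would break the privacy ",
         "guarantee")
  }
  scales <- laplace_scales(data$d, b, budget)
  noisy <- with_seed(spawn_seed(seed, "noise"), perturb_stats(clean, scales))
  assign(key, TRUE, envir = .release_registry)
  structure(list(
    stats = noisy, bounds = b, spec = spec, budget = budget,
    d = data$d, n = data$n, seed = as.integer(seed),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "private_release")
}

#' @export
print.private_release <- function(x, ...) {
  cat(sprintf(paste0("<private_release> d = %d, n = %d, epsilon = %g, ",
                     "split = (%g, %g, %g), seed = %d\n"),
              x$d, x$n, x$budget$epsilon, x$budget$p1, x$budget$p2,
              x$budget$p3, x$seed))
  invisible(x)
}

#' Clear the release double-spend registry
#'
#' Intended for tests and for starting a genuinely new analysis session.
#' @return Invisibly, the number of entries removed.
#' @export
reset_release_registry <- function() {
  n <- length(ls(.release_registry))
  rm(list = ls(.release_registry), envir = .release_registry)
  invisible(n)
}
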