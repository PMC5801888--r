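# Posterior computation from (possibly noisy) sufficient statistics:
# conjugate fixed-precision path, hierarchical Gamma-prior path via Gibbs
# sampling, and point prediction.

#' Prior specification for the precision parameters
#'
#' In `fixed` mode the noise precision `lambda` and the coefficient prior
#' precision `lambda0` are known constants and the coefficient posterior is
#' Gaussian in closed form. In `hierarchical` mode both get Gamma priors
#' (shape/rate, so mean `a/b` and variance `a/b^2`); the defaults
#' `Gamma(2, 2)` have mean 1 and variance 1/2, a weakly informative choice
#' concentrated on sensible positive precisions.
#'
#' @param mode `"fixed"` or `"hierarchical"`.
#' @param lambda,lambda0 fixed precisions (fixed mode).
#' @param a,b Gamma shape/rate for `lambda` (hierarchical mode).
#' @param a0,b0 Gamma shape/rate for `lambda0` (hierarchical mode).
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(mode = c("fixed", "hierarchical"),
                       lambda = 1, lambda0 = 1,
                       a = 2, b = 2, a0 = 2, b0 = 2) {
  mode <- match.arg(mode)
  stopifnot(lambda > 0, lambda0 > 0, a > 0, b > 0, a0 > 0, b0 > 0)
  structure(list(mode = mode, lambda = lambda, lambda0 = lambda0,
                 a = a, b = b, a0 = a0, b0 = b0),
            class = "prior_spec")
}

#' Gamma prior moments
#'
#' Mean `a/b` and variance `a/b^2` of a shape/rate Gamma distribution, as
#' used for the precision priors.
#'
#' @param a,b positive shape and rate.
#' @return Named vector `c(mean, var)`.
#' @export
gamma_prior_moments <- function(a, b) {
  stopifnot(a > 0, b > 0)
  c(mean = a / b, var = a / b^2)
}

#' Project a symmetric matrix to the positive semidefinite cone
#'
#' Noisy releases of `nxx` need not be PSD; eigenvalues below zero are
#' clipped to exactly zero, which is the nearest PSD matrix in Frobenius
#' norm. This is post-processing of the release, so it costs no privacy.
#'
#' @param M symmetric numeric matrix.
#' @param tol symmetry tolerance.
#' @return Symmetric PSD matrix; PSD inputs are returned unchanged.
#' @export
psd_repair <- function(M, tol = 1e-8) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M) || max(abs(M - t(M))) > tol * max(1, max(abs(M)))) {
    stop("psd_repair requires a symmetric matrix")
  }
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (all(e$values >= 0)) return(M)
  lam <- pmax(e$values, 0)
  R <- e$vectors %*% (lam * t(e$vectors))
  (R + t(R)) / 2
}

# repaired, coherent view of possibly-noisy statistics for inference:
# nxx projected to PSD, nyy floored at 0
coherent_stats <- function(stats) {
  if (!stats$is_noisy) return(stats)
  stats$nxx <- psd_repair(stats$nxx)
  stats$nxx[lower.tri(stats$nxx)] <- t(stats$nxx)[lower.tri(stats$nxx)]
  stats$nyy <- max(stats$nyy, 0)
  stats
}

#' Conjugate posterior with fixed precisions
#'
#' With known precisions the coefficient posterior is Gaussian with
#' precision `Lambda* = lambda0 I + lambda nxx` and mean
#' `mu* = Lambda*^{-1} (lambda nxy)`. Noisy `nxx` is PSD-repaired first;
#' `lambda0 > 0` then guarantees `Lambda*` is positive definite.
#'
#' @param stats `suff_stats` (clean or a noisy release).
#' @param lambda positive noise precision.
#' @param lambda0 positive coefficient prior precision.
#' @return Object of class `posterior_fixed` with `mu` (posterior mean) and
#'   `Lambda` (posterior precision matrix).
#' @export
posterior_fixed <- function(stats, lambda = 1, lambda0 = 1) {
  stopifnot(inherits(stats, "suff_stats"), lambda > 0, lambda0 > 0)
  st <- coherent_stats(stats)
  Lambda <- lambda0 * diag(st$d) + lambda * st$nxx
  mu <- solve(Lambda, lambda * st$nxy)
  structure(list(mu = as.numeric(mu), Lambda = Lambda,
                 lambda = lambda, lambda0 = lambda0, d = st$d),
            class = "posterior_fixed")
}

#' @export
print.posterior_fixed <- function(x, ...) {
  cat(sprintf("<posterior_fixed> d = %d, lambda = %g, lambda0 = %g\n",
              x$d, x$lambda, x$lambda0))
  cat("mu*:", format(utils::head(x$mu, 8), digits = 4),
      if (x$d > 8) "..." else "", "\n")
  invisible(x)
}

#' Hierarchical posterior from sufficient statistics via Gibbs sampling
#'
#' Under Gamma priors on both precisions the model is conditionally
#' conjugate given the sufficient statistics: `beta | lambda, lambda0` is
#' Gaussian (the fixed-precision posterior), `lambda | beta` is
#' `Gamma(a + n/2, b + Q(beta)/2)` with the residual quadratic form
#' `Q(beta) = beta' nxx beta - 2 beta' nxy + nyy` (floored at 0, which can
#' bind for noisy releases), and `lambda0 | beta` is
#' `Gamma(a0 + d/2, b0 + |beta|^2 / 2)`. A Gibbs sweep over these exact
#' conditionals targets the same posterior the likelihood-in-statistics form
#' defines; accuracy is certified against the conjugate closed form in the
#' test suite rather than by the algorithm's label.
#'
#' @param stats `suff_stats`; noisy releases are first made coherent
#'   (PSD repair, floors).
#' @param priors a [prior_spec()] in hierarchical mode.
#' @param m number of retained posterior draws (default 5000).
#' @param burnin discarded warm-up sweeps.
#' @param seed optional seed for the sampler stream.
#' @return Object of class `posterior_samples`: matrix `beta` (`m x d`),
#'   vectors `lambda`, `lambda0`, and `diagnostics` (minimum effective sample
#'   size across parameters and a `converged` flag; `converged = FALSE` is a
#'   warning carried in the result, not an error).
#' @export
fit_hierarchical <- function(stats, priors = prior_spec("hierarchical"),
                             m = 5000, burnin = 500, seed = NULL) {
  stopifnot(inherits(stats, "suff_stats"), inherits(priors, "prior_spec"))
  if (m < 1) stop("m must be at least 1")
  st <- coherent_stats(stats)
  d <- st$d
  n <- st$n
  # one-time eigendecomposition of (repaired) nxx makes every conditional
  # Gaussian update exact and stable: Lambda = V (lambda0 + lambda * ev) V'
  eg <- eigen(st$nxx, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  V <- eg$vectors
  bproj <- as.numeric(crossprod(V, st$nxy))
  with_seed(seed, {
    lambda <- priors$a / priors$b
    lambda0 <- priors$a0 / priors$b0
    B <- matrix(0, m, d)
    L <- numeric(m)
    L0 <- numeric(m)
    total <- burnin + m
    for (it in seq_len(total)) {
      prec <- lambda0 + lambda * ev
      mu <- V %*% (lambda * bproj / prec)
      beta <- as.numeric(mu + V %*% (rnorm(d) / sqrt(prec)))
      # numerical guards: the quadratic form is floored at 0, and the
      # precision draws are clamped to a wide positive range. For repaired
      # noisy releases the likelihood can be unbounded along null
      # directions of nxx; without the clamp the chain can diverge to
      # non-finite values instead of merely scoring badly.
      beta[!is.finite(beta)] <- 0
      beta <- pmin(pmax(beta, -1e8), 1e8)
      q <- max(0, as.numeric(t(beta) %*% st$nxx %*% beta -
                               2 * sum(beta * st$nxy) + st$nyy))
      lambda <- min(max(rgamma(1, shape = priors$a + n / 2,
                               rate = priors$b + q / 2), 1e-10), 1e10)
      lambda0 <- min(max(rgamma(1, shape = priors$a0 + d / 2,
                                rate = priors$b0 + sum(beta^2) / 2),
                         1e-10), 1e10)
      if (it > burnin) {
        B[it - burnin, ] <- beta
        L[it - burnin] <- lambda
        L0[it - burnin] <- lambda0
      }
    }
    ess <- c(apply(B, 2, ess_acf), ess_acf(L), ess_acf(L0))
    diag_ok <- min(ess) >= min(100, m / 10)
    if (!diag_ok) {
      warning("hierarchical sampler may not have converged (min ESS = ",
              round(min(ess)), ")")
    }
    structure(list(beta = B, lambda = L, lambda0 = L0, m = as.integer(m),
                   d = d, priors = priors,
                   diagnostics = list(min_ess = min(ess), converged = diag_ok)),
              class = "posterior_samples")
  })
}

# effective sample size from the initial-positive-sequence autocorrelation sum
ess_acf <- function(x) {
  m <- length(x)
  if (m < 10 || sd(x) == 0) return(m)
  rho <- as.numeric(acf(x, lag.max = min(m - 1, 200), plot = FALSE)$acf)[-1]
  neg <- which(rho < 0)
  if (length(neg) > 0) rho <- rho[seq_len(neg[1] - 1)]
  m / (1 + 2 * sum(rho))
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples> d = %d, m = %d, min ESS = %.0f%s\n",
              x$d, x$m, x$diagnostics$min_ess,
              if (x$diagnostics$converged) "" else " (convergence warning)"))
  invisible(x)
}

#' Predict targets for new inputs
#'
#' Fixed mode: `yhat = X mu*`. Hierarchical mode: the posterior-predictive
#' mean, i.e. `X beta^(k)` averaged over the retained draws.
#'
#' @param object a `posterior_fixed` or `posterior_samples` fit.
#' @param newdata numeric matrix `t x d` of new inputs (already on the
#'   training scale: preprocessed and, by default, clipped with the training
#'   bounds).
#' @param ... unused.
#' @return Numeric vector of `t` predictions.
#' @export
predict.posterior_fixed <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$d) {
    stop("newdata has ", ncol(X), " columns, model has d = ", object$d)
  }
  as.numeric(X %*% object$mu)
}

#' @rdname predict.posterior_fixed
#' @export
predict.posterior_samples <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$d) {
    stop("newdata has ", ncol(X), " columns, model has d = ", object$d)
  }
  as.numeric(X %*% colMeans(object$beta))
}
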