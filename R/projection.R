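# Outlier projection (clipping) and the sd-multiplier parametrization of the
# clipping bounds. Tight bounds shrink the sensitivity of the released
# statistics, so less privacy noise is needed; the price is clipping bias.

#' Clipping bounds for inputs and targets
#'
#' @param bx positive bound for input entries (clip to `[-bx, bx]`).
#' @param by positive bound for targets (clip to `[-by, by]`).
#' @return Object of class `bounds`.
#' @export
bounds <- function(bx, by) {
  stopifnot(is.numeric(bx), is.numeric(by), length(bx) == 1, length(by) == 1)
  if (!(bx > 0) || !(by > 0)) stop("clipping bounds must be strictly positive")
  structure(list(bx = bx, by = by), class = "bounds")
}

#' Bounds parametrized as standard-deviation multipliers
#'
#' The bounds are expressed as `Bx = omega_x * sigma_x`, `By = omega_y *
#' sigma_y`, where the sigmas are the standard deviations of the (private,
#' preprocessed) training inputs pooled over all coordinates and of the
#' targets. The multipliers are what the auxiliary-data grid search tunes.
#'
#' @param omega_x,omega_y positive sd multipliers.
#' @param sigma_x,sigma_y standard deviations; `NA` until materialized
#'   against a concrete dataset.
#' @return Object of class `threshold_spec`.
#' @export
threshold_spec <- function(omega_x, omega_y, sigma_x = NA_real_,
                           sigma_y = NA_real_) {
  stopifnot(omega_x > 0, omega_y > 0)
  structure(list(omega_x = omega_x, omega_y = omega_y,
                 sigma_x = sigma_x, sigma_y = sigma_y),
            class = "threshold_spec")
}

#' Estimate the clipping standard deviations from a dataset
#'
#' `sigma_x` is the standard deviation of the input entries pooled over all
#' `n * d` values; `sigma_y` that of the targets. The population convention
#' (divide by the count, not count - 1) is used; at realistic n the
#' difference is immaterial but the choice is fixed for reproducibility.
#'
#' @param data a [labeled_dataset()] (the private training set, after
#'   preprocessing).
#' @return Named numeric vector `c(sigma_x = ..., sigma_y = ...)`.
#' @export
estimate_sigmas <- function(data) {
  stopifnot(inherits(data, "labeled_dataset"), data$n >= 2)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  sx <- pop_sd(as.numeric(data$X))
  sy <- pop_sd(data$y)
  if (sx == 0) stop("all input entries are equal: sigma_x = 0, bounds would collapse")
  if (sy == 0) stop("all targets are equal: sigma_y = 0, bounds would collapse")
  c(sigma_x = sx, sigma_y = sy)
}

#' Materialize clipping bounds from a threshold specification
#'
#' @param spec a [threshold_spec()] with sigmas filled in, or the sigmas can
#'   be supplied here.
#' @param sigmas optional named vector from [estimate_sigmas()].
#' @return A [bounds()] object with `bx = omega_x * sigma_x`,
#'   `by = omega_y * sigma_y`.
#' @export
bounds_from_spec <- function(spec, sigmas = NULL) {
  stopifnot(inherits(spec, "threshold_spec"))
  if (!is.null(sigmas)) {
    spec$sigma_x <- unname(sigmas[["sigma_x"]])
    spec$sigma_y <- unname(sigmas[["sigma_y"]])
  }
  if (is.na(spec$sigma_x) || is.na(spec$sigma_y)) {
    stop("sigma_x / sigma_y are not set; estimate them from the private data")
  }
  if (!(spec$sigma_x > 0) || !(spec$sigma_y > 0)) {
    stop("sigmas must be strictly positive")
  }
  bounds(spec$omega_x * spec$sigma_x, spec$omega_y * spec$sigma_y)
}

#' Project a dataset to clipping bounds
#'
#' Every input entry is clipped to `[-Bx, Bx]` and every target to
#' `[-By, By]`; interior values are untouched, so the operation is
#' idempotent. After projection the sup-norm of every input row is at most
#' `Bx` and every |target| at most `By`, which is what bounds the
#' sensitivity of the sufficient statistics.
#'
#' @param data a [labeled_dataset()].
#' @param b a [bounds()] object.
#' @return The projected `labeled_dataset`.
#' @export
project_dataset <- function(data, b) {
  stopifnot(inherits(data, "labeled_dataset"), inherits(b, "bounds"))
  X <- clip_values(data$X, b$bx)
  y <- clip_values(data$y, b$by)
  labeled_dataset(X, y, private = data$private)
}

#' Clip numeric values to a symmetric interval
#'
#' The elementwise transform `phi_B(v) = max(-B, min(v, B))`. Exposed because
#' test inputs are passed through the same transform as training inputs (the
#' fitted model is a regression on the clipped scale).
#'
#' @param v numeric vector or matrix.
#' @param b positive bound.
#' @return `v` with every entry clipped to `[-b, b]`.
#' @export
clip_values <- function(v, b) {
  stopifnot(b > 0)
  v[v > b] <- b
  v[v < -b] <- -b
  v
}
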