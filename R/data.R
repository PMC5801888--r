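# Dataset container, preprocessing transforms, sufficient statistics.

#' Construct a labeled dataset
#'
#' Bundles an input matrix (rows = samples, columns = features) with a scalar
#' target per sample, e.g. gene-expression profiles of cell lines with a
#' log-IC50 drug response. Rows with a missing target are dropped; missing
#' inputs are an error (no imputation).
#'
#' @param X numeric matrix, `n x d`.
#' @param y numeric vector of length `n`.
#' @param private logical; whether this dataset requires privacy protection.
#' @return An object of class `labeled_dataset` with fields `X`, `y`, `n`,
#'   `d`, `private`.
#' @export
labeled_dataset <- function(X, y, private = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) {
    stop("nrow(X) [", nrow(X), "] must equal length(y) [", length(y), "]")
  }
  keep <- !is.na(y)
  if (!all(keep)) {
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  if (anyNA(X)) stop("X contains missing values; imputation is not supported")
  structure(
    list(X = X, y = y, n = nrow(X), d = ncol(X), private = isTRUE(private)),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> n = %d, d = %d, %s\n", x$n, x$d,
              if (x$private) "private" else "non-private"))
  invisible(x)
}

#' Center the columns of an input matrix
#'
#' Removes the mean from each feature. The returned column means are applied
#' to test data so that train and test live in the same space.
#'
#' @param X numeric matrix with at least one row.
#' @return List with `X` (centered matrix) and `means` (column means).
#' @export
center_features <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 1) stop("cannot center an empty matrix")
  means <- colMeans(X)
  list(X = sweep(X, 2, means, "-"), means = means)
}

#' Scale each row of a matrix to unit Euclidean norm
#'
#' Equalizes the contribution of each sample and focuses the analysis on the
#' relative values of the features within a sample.
#'
#' @param X numeric matrix with no all-zero rows.
#' @return Matrix whose rows all have L2 norm 1.
#' @export
l2_normalize_rows <- function(X) {
  X <- as.matrix(X)
  nrm <- sqrt(rowSums(X^2))
  bad <- which(nrm == 0)
  if (length(bad) > 0) {
    stop("cannot L2-normalize all-zero row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  X / nrm
}

#' Center a target vector
#'
#' @param y numeric vector with at least one element.
#' @return List with `y` (centered) and `mean` (to add back to predictions).
#' @export
center_targets <- function(y) {
  y <- as.numeric(y)
  if (length(y) < 1) stop("cannot center an empty target vector")
  m <- mean(y)
  list(y = y - m, mean = m)
}

#' Preprocess a labeled dataset
#'
#' Standard pipeline: center each feature, scale each row to unit L2 norm,
#' center the targets. Returns the fitted transform parameters so the same
#' shifts can be applied to held-out data with [apply_preprocess()].
#'
#' @param data a [labeled_dataset()].
#' @return List with `data` (transformed dataset), `x_means`, `y_mean`.
#' @export
preprocess <- function(data) {
  stopifnot(inherits(data, "labeled_dataset"))
  cf <- center_features(data$X)
  Xn <- l2_normalize_rows(cf$X)
  ct <- center_targets(data$y)
  list(data = labeled_dataset(Xn, ct$y, private = data$private),
       x_means = cf$means, y_mean = ct$mean)
}

#' Apply training preprocessing to new inputs
#'
#' Centers columns with the training column means, then row-normalizes.
#'
#' @param X numeric matrix of new inputs.
#' @param pp result of [preprocess()] (or any list with `x_means`).
#' @return Transformed matrix.
#' @export
apply_preprocess <- function(X, pp) {
  l2_normalize_rows(sweep(as.matrix(X), 2, pp$x_means, "-"))
}

#' Compute the sufficient statistics of a dataset
#'
#' For the Bayesian linear model everything the data contribute is captured
#' by `nxx = sum_i x_i x_i^T`, `nxy = sum_i x_i y_i` and `nyy = sum_i y_i^2`,
#' together with the (public) sample count. These are the only quantities
#' ever released under privacy.
#'
#' @param data a [labeled_dataset()], or a numeric matrix if `y` is given.
#' @param y optional numeric targets when `data` is a plain matrix.
#' @return An object of class `suff_stats` with fields `nxx` (exactly
#'   symmetric `d x d`), `nxy` (length `d`), `nyy` (scalar), `n`, `d`,
#'   `is_noisy = FALSE`.
#' @export
sufficient_stats <- function(data, y = NULL) {
  if (inherits(data, "labeled_dataset")) {
    X <- data$X
    y <- data$y
  } else {
    X <- as.matrix(data)
    y <- as.numeric(y)
  }
  nxx <- crossprod(X)
  # enforce exact symmetry: keep upper triangle, mirror to lower
  nxx[lower.tri(nxx)] <- t(nxx)[lower.tri(nxx)]
  new_suff_stats(nxx = unname(nxx), nxy = unname(as.numeric(crossprod(X, y))),
                 nyy = sum(y^2), n = nrow(X), is_noisy = FALSE)
}

new_suff_stats <- function(nxx, nxy, nyy, n, is_noisy) {
  d <- length(nxy)
  stopifnot(is.matrix(nxx), nrow(nxx) == d, ncol(nxx) == d)
  if (!identical(nxx, t(nxx))) stop("nxx must be exactly symmetric")
  structure(list(nxx = nxx, nxy = nxy, nyy = nyy, n = as.integer(n),
                 d = d, is_noisy = isTRUE(is_noisy)),
            class = "suff_stats")
}

#' @export
print.suff_stats <- function(x, ...) {
  cat(sprintf("<suff_stats> d = %d, n = %d, %s\n", x$d, x$n,
              if (x$is_noisy) "noisy (private release)" else "clean"))
  invisible(x)
}

#' Combine sufficient statistics of several datasets
#'
#' Statistics are additive: the statistics of a concatenation of datasets are
#' the entry-wise sums of the parts. This is how a clean internal dataset is
#' pooled with one or more noisy private releases.
#'
#' @param ... `suff_stats` objects (or a single list of them).
#' @return A `suff_stats` object; `is_noisy` is `TRUE` if any part is noisy.
#' @export
combine_stats <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && !inherits(parts[[1]], "suff_stats")) {
    parts <- parts[[1]]
  }
  stopifnot(length(parts) >= 1)
  lapply(parts, function(p) stopifnot(inherits(p, "suff_stats")))
  d <- parts[[1]]$d
  for (p in parts) {
    if (p$d != d) stop("dimension mismatch in combine_stats: ", p$d, " vs ", d)
  }
  out <- parts[[1]]
  if (length(parts) > 1) {
    for (p in parts[-1]) {
      out$nxx <- out$nxx + p$nxx
      out$nxy <- out$nxy + p$nxy
      out$nyy <- out$nyy + p$nyy
      out$n <- out$n + p$n
      out$is_noisy <- out$is_noisy || p$is_noisy
    }
  }
  out$nxx[lower.tri(out$nxx)] <- t(out$nxx)[lower.tri(out$nxx)]
  out
}
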