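# Synthetic data generators: the auxiliary/tuning generative model, a
# heavy-tailed stress variant, and a drug-sensitivity-panel-like fixture.

#' Generate an auxiliary synthetic regression dataset
#'
#' The generative model used for all tuning and synthetic experiments:
#' coefficients `beta ~ N(0, precision lambda0 * I)` drawn once, inputs
#' `x_i ~ N(0, I)` i.i.d. (or, for the heavy-tailed stress variant, each
#' input coordinate i.i.d. Student-t with 1 degree of freedom), targets
#' `y_i = x_i' beta + noise` with noise precision `lambda`. Defaults
#' `lambda = lambda0 = 1` fix the precisions at the prior means.
#'
#' @param n number of samples.
#' @param d dimensionality.
#' @param lambda noise precision (variance `1/lambda`).
#' @param lambda0 coefficient prior precision.
#' @param tail `"gaussian"` (default) or `"student_t_df1"` for the
#'   heavy-tailed input variant.
#' @param seed optional seed (the generator is deterministic given it).
#' @param beta optional fixed coefficient vector; drawn if `NULL`.
#' @param private privacy flag of the returned dataset.
#' @return List with `data` (a [labeled_dataset()]) and `beta` (the true
#'   coefficients, for recovery checks).
#' @export
generate_auxiliary <- function(n, d, lambda = 1, lambda0 = 1,
                               tail = c("gaussian", "student_t_df1"),
                               seed = NULL, beta = NULL, private = TRUE) {
  tail <- match.arg(tail)
  stopifnot(n >= 1, d >= 1, lambda > 0, lambda0 > 0)
  with_seed(seed, {
    if (is.null(beta)) beta <- rnorm(d, sd = 1 / sqrt(lambda0))
    X <- if (tail == "gaussian") {
      matrix(rnorm(n * d), n, d)
    } else {
      matrix(rt(n * d, df = 1), n, d)
    }
    y <- as.numeric(X %*% beta) + rnorm(n, sd = 1 / sqrt(lambda))
    list(data = labeled_dataset(X, y, private = private), beta = beta)
  })
}

#' Generate a drug-sensitivity-panel-like synthetic fixture
#'
#' A stand-in for a cell-line drug screen: one shared feature matrix
#' (hundreds of "cell lines" by tens of "genes"), one target column per
#' "drug" generated from the linear model with drug-specific coefficients,
#' and targets masked missing completely at random to mimic unmeasured drug
#' responses. Entirely synthetic; no real screen data are involved.
#'
#' @param n_cell_lines number of samples (rows of the shared matrix).
#' @param n_features number of features.
#' @param n_drugs number of target columns.
#' @param missing_rate probability in `[0, 1]` that a target is missing.
#' @param lambda,lambda0 precisions of the generative model.
#' @param seed optional seed.
#' @return List with `X` (feature matrix with row/column names), `Y`
#'   (`n_cell_lines x n_drugs` target matrix with `NA`s), `betas`
#'   (`n_features x n_drugs`), and `datasets` (per-drug
#'   [labeled_dataset()]s with missing-target rows dropped).
#' @export
generate_gdsc_like_fixture <- function(n_cell_lines = 500, n_features = 10,
                                       n_drugs = 5, missing_rate = 0.1,
                                       lambda = 1, lambda0 = 1, seed = NULL) {
  stopifnot(missing_rate >= 0, missing_rate <= 1)
  with_seed(seed, {
    X <- matrix(rnorm(n_cell_lines * n_features), n_cell_lines, n_features)
    rownames(X) <- sprintf("CL%04d", seq_len(n_cell_lines))
    colnames(X) <- sprintf("G%03d", seq_len(n_features))
    betas <- matrix(rnorm(n_features * n_drugs, sd = 1 / sqrt(lambda0)),
                    n_features, n_drugs)
    Y <- X %*% betas + matrix(rnorm(n_cell_lines * n_drugs,
                                    sd = 1 / sqrt(lambda)),
                              n_cell_lines, n_drugs)
    mask <- matrix(runif(n_cell_lines * n_drugs) < missing_rate,
                   n_cell_lines, n_drugs)
    Y[mask] <- NA_real_
    colnames(Y) <- sprintf("drug%02d", seq_len(n_drugs))
    rownames(Y) <- rownames(X)
    datasets <- lapply(seq_len(n_drugs), function(j) {
      keep <- !is.na(Y[, j])
      if (!any(keep)) {
        return(labeled_dataset(X[integer(0), , drop = FALSE], numeric(0)))
      }
      labeled_dataset(X[keep, , drop = FALSE], Y[keep, j])
    })
    names(datasets) <- colnames(Y)
    list(X = X, Y = Y, betas = betas, datasets = datasets)
  })
}

#' Write a synthetic fixture to delimited text files
#'
#' Emits the same dialect the loaders read: one expression matrix file
#' (first column = sample ID) and one two-column (ID, target) file per drug,
#' with missing targets written as `NA`.
#'
#' @param fixture result of [generate_gdsc_like_fixture()].
#' @param dir output directory (created if needed).
#' @param sep field separator, `"\t"` (default) or `","`.
#' @return Invisibly, the paths written (`x` and per-drug target files).
#' @export
write_fixture <- function(fixture, dir, sep = "\t") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (sep == ",") "csv" else "tsv"
  x_path <- file.path(dir, paste0("expression.", ext))
  write_matrix(fixture$X, x_path, sep = sep)
  y_paths <- vapply(colnames(fixture$Y), function(drug) {
    p <- file.path(dir, paste0(drug, ".", ext))
    df <- data.frame(sample_id = rownames(fixture$Y),
                     target = fixture$Y[, drug])
    write.table(df, p, sep = sep, quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(c(x = x_path, y_paths))
}
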