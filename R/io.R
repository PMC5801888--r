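# Delimited-text and JSON round-trips for all serialized types.

detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a numeric matrix from delimited text
#'
#' Expects a header row and a first column of sample IDs; TSV by default,
#' CSV if the extension is `.csv` or `sep = ","`. Ragged rows are rejected
#' with the offending line number.
#'
#' @param path file path.
#' @param sep field separator; inferred from the extension if `NULL`.
#' @return Numeric matrix with row names from the ID column.
#' @export
read_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_sep(path, sep)
  nf <- count.fields(path, sep = sep, quote = "\"")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop("ragged row in ", path, ": line ", bad, " has ", nf[bad],
         " fields, expected ", nf[1])
  }
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix file needs an ID column plus data: ", path)
  ids <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(M)) stop("non-numeric entries in matrix file: ", path)
  rownames(M) <- ids
  M
}

#' Write a numeric matrix as delimited text
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces the doubles exactly.
#'
#' @param M numeric matrix (row names used as sample IDs).
#' @param path output path.
#' @param sep field separator (tab default).
#' @param id_col name of the ID column in the header.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(M, path, sep = "\t", id_col = "sample_id") {
  M <- as.matrix(M)
  ids <- rownames(M)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(nrow(M)))
  body <- apply(M, 2, function(col) sprintf("%.17g", col))
  if (nrow(M) == 1) body <- matrix(body, nrow = 1)
  df <- data.frame(ids, body, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(M))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a labeled dataset from an inputs file and a targets file
#'
#' The inputs file holds the feature matrix, the targets file two columns
#' (ID, target). Rows are joined on ID; unmatched rows and rows with a
#' missing target are dropped, with a message stating how many.
#'
#' @param x_path path to the feature matrix file.
#' @param y_path path to the two-column target file.
#' @param private privacy flag of the resulting dataset.
#' @param sep separator override for both files.
#' @return A [labeled_dataset()].
#' @export
read_labeled_dataset <- function(x_path, y_path, private = TRUE, sep = NULL) {
  X <- read_matrix(x_path, sep = sep)
  ysep <- detect_sep(y_path, sep)
  ydf <- read.delim(y_path, sep = ysep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(ydf) < 2) stop("target file needs (ID, target) columns: ", y_path)
  yid <- as.character(ydf[[1]])
  y <- suppressWarnings(as.numeric(ydf[[2]]))
  common <- intersect(rownames(X), yid)
  dropped_join <- (nrow(X) - length(common)) + (length(yid) - length(common))
  yv <- y[match(common, yid)]
  n_missing <- sum(is.na(yv))
  if (dropped_join > 0 || n_missing > 0) {
    message("read_labeled_dataset: dropped ", dropped_join,
            " unmatched row(s) and ", n_missing, " missing target(s)")
  }
  labeled_dataset(X[common, , drop = FALSE], yv, private = private)
}

# full-precision JSON: 17 significant digits are enough for a write/read
# round trip to reproduce every double bit-exactly
write_json_full <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Serialize a private release artifact to JSON
#'
#' The artifact is self-describing: dimension, sample count, budget and
#' split, bounds, threshold spec, the flattened upper triangle of the noisy
#' `nxx`, the noisy `nxy` and `nyy`, the seed record and a timestamp.
#' Statistics survive a write/read round trip bit-exactly.
#'
#' @param release a `private_release` from [dp_release()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_release <- function(release, path) {
  stopifnot(inherits(release, "private_release"))
  s <- release$stats
  payload <- list(
    format = "privlr_release", version = 1L,
    d = s$d, n = s$n,
    epsilon = release$budget$epsilon,
    split = c(release$budget$p1, release$budget$p2, release$budget$p3),
    bounds = list(bx = release$bounds$bx, by = release$bounds$by),
    thresholds = unclass(release$spec),
    nxx_upper = s$nxx[upper_index(s$d)],
    nxy = s$nxy, nyy = s$nyy,
    seed = release$seed, created = release$created
  )
  write_json_full(payload, path)
}

#' Read a private release artifact from JSON
#'
#' @param path path written by [write_release()].
#' @return A `private_release` object.
#' @export
read_release <- function(path) {
  if (!file.exists(path)) stop("release file not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "privlr_release")) {
    stop("not a release artifact: ", path)
  }
  d <- as.integer(p$d)
  nxx <- matrix(0, d, d)
  nxx[upper_index(d)] <- as.numeric(p$nxx_upper)
  nxx[lower.tri(nxx)] <- t(nxx)[lower.tri(nxx)]
  stats <- new_suff_stats(nxx, as.numeric(p$nxy), as.numeric(p$nyy),
                          n = p$n, is_noisy = TRUE)
  structure(list(
    stats = stats,
    bounds = bounds(p$bounds$bx, p$bounds$by),
    spec = threshold_spec(p$thresholds$omega_x, p$thresholds$omega_y,
                          p$thresholds$sigma_x, p$thresholds$sigma_y),
    budget = privacy_budget(p$epsilon, as.numeric(p$split)),
    d = d, n = as.integer(p$n), seed = as.integer(p$seed), created = p$created
  ), class = "private_release")
}

#' Serialize a posterior to JSON
#'
#' Fixed mode stores `mu` and the full `Lambda`; hierarchical mode stores
#' the draw arrays.
#'
#' @param posterior a `posterior_fixed` or `posterior_samples`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_posterior <- function(posterior, path) {
  if (inherits(posterior, "posterior_fixed")) {
    payload <- list(format = "privlr_posterior", mode = "fixed",
                    d = posterior$d, mu = posterior$mu,
                    Lambda = as.numeric(posterior$Lambda),
                    lambda = posterior$lambda, lambda0 = posterior$lambda0)
  } else if (inherits(posterior, "posterior_samples")) {
    payload <- list(format = "privlr_posterior", mode = "hierarchical",
                    d = posterior$d, m = posterior$m,
                    beta = as.numeric(posterior$beta),
                    lambda = posterior$lambda, lambda0 = posterior$lambda0,
                    diagnostics = posterior$diagnostics)
  } else stop("not a posterior object")
  write_json_full(payload, path)
}

#' Read a posterior from JSON
#'
#' @param path path written by [write_posterior()].
#' @return A `posterior_fixed` or `posterior_samples` object.
#' @export
read_posterior <- function(path) {
  if (!file.exists(path)) stop("posterior file not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "privlr_posterior")) stop("not a posterior: ", path)
  d <- as.integer(p$d)
  if (identical(p$mode, "fixed")) {
    structure(list(mu = as.numeric(p$mu),
                   Lambda = matrix(as.numeric(p$Lambda), d, d),
                   lambda = p$lambda, lambda0 = p$lambda0, d = d),
              class = "posterior_fixed")
  } else {
    m <- as.integer(p$m)
    structure(list(beta = matrix(as.numeric(p$beta), m, d),
                   lambda = as.numeric(p$lambda),
                   lambda0 = as.numeric(p$lambda0),
                   m = m, d = d, diagnostics = p$diagnostics),
              class = "posterior_samples")
  }
}

#' Read a JSON run configuration
#'
#' @param path JSON file of named settings.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
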