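# shared fixture builders; everything is generated in code

random_dataset <- function(n = 20, d = 3, seed = NULL, private = TRUE) {
  privlr:::with_seed(seed, {
    labeled_dataset(matrix(rnorm(n * d), n, d), rnorm(n), private = private)
  })
}

# direct Bayesian ridge posterior from (X, y), no statistics shortcut;
# independent oracle for the conjugate path
direct_ridge_posterior <- function(X, y, lambda, lambda0) {
  d <- ncol(X)
  Lambda <- lambda0 * diag(d) + lambda * t(X) %*% X
  list(mu = as.numeric(solve(Lambda, lambda * t(X) %*% y)), Lambda = Lambda)
}
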