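# Shared fixtures and independent oracles used across tests.

# Closed-form weighted least squares, independent of the package's fitting
# code: solves (X' W X) b = X' W y by explicit dense linear algebra.
wls_oracle <- function(X, y, w) {
  W <- diag(w)
  drop(solve(t(X) %*% W %*% X, t(X) %*% W %*% y))
}

# Small exactly-linear dataset: y = 1 + 2 d + 3 x with no noise.
toy_linear_dataset <- function() {
  d <- c(1, 0, 1, 0, 1, 0)
  x <- c(0, 1, 2, 3, 4, 5)
  observational_dataset(1 + 2 * d + 3 * x, d, cbind(x = x))
}

# Build an or_fit object directly from known coefficients, for checking the
# prediction/averaging machinery against hand computations.
manual_or_fit <- function(xi, link = "identity", terms = "x") {
  structure(list(xi = xi,
                 spec = model_spec(link, terms = terms),
                 weights_used = rep(1, 2), converged = TRUE, gam = NULL,
                 treatment_name = "d"),
            class = "or_fit")
}

# CSV fixture written on the fly.
write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
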