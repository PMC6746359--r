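# Internal helpers shared across modules.

.expit <- function(x) stats::plogis(x)

# Clip probabilities away from 0/1. eps = 0 is a no-op.
.clip_probs <- function(p, eps) {
  if (eps <= 0) return(p)
  pmin(pmax(p, eps), 1 - eps)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_prob_vector <- function(ps, n = NULL, open = TRUE) {
  if (!is.numeric(ps) || anyNA(ps)) .stopf("propensity scores must be numeric with no missing values")
  if (!is.null(n) && length(ps) != n) .stopf("propensity vector has length %d, expected %d", length(ps), n)
  if (open) {
    if (any(ps <= 0) || any(ps >= 1)) .stopf("propensity scores must lie strictly inside (0, 1)")
  } else {
    if (any(ps < 0) || any(ps > 1)) .stopf("propensity scores must lie in [0, 1]")
  }
  invisible(ps)
}

# Newton-Raphson fit of a binomial-logit GLM score with optional unit weights:
# solves sum_i w_i x_i (d_i - expit(x_i'b)) = 0. Used for propensity models and
# for the per-draw refits inside the Bayesian bootstrap, where a warm start
# makes the refit cheap.
.logit_fit <- function(Xmat, d, w = NULL, start = NULL, tol = 1e-8, maxit = 100L) {
  n <- nrow(Xmat)
  if (is.null(w)) w <- rep(1, n)
  beta <- if (is.null(start)) numeric(ncol(Xmat)) else start
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(Xmat %*% beta)
    p <- stats::plogis(eta)
    g <- crossprod(Xmat, w * (d - p))
    H <- crossprod(Xmat, Xmat * (w * p * (1 - p)))
    step <- tryCatch(drop(solve(H, g)), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) {
      return(.logit_fit_glm(Xmat, d, w))
    }
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  fitted <- stats::plogis(drop(Xmat %*% beta))
  dev <- -2 * sum(d * log(pmax(fitted, 1e-300)) + (1 - d) * log(pmax(1 - fitted, 1e-300)))
  list(coefficients = beta, fitted = fitted, converged = converged,
       iter = it, deviance = dev)
}

# Fallback via IRLS with step control from stats::glm.fit.
.logit_fit_glm <- function(Xmat, d, w) {
  f <- suppressWarnings(stats::glm.fit(Xmat, d, weights = w, family = stats::binomial()))
  list(coefficients = f$coefficients, fitted = f$fitted.values,
       converged = f$converged, iter = f$iter, deviance = f$deviance)
}

# Column-major symmetric fill used by the vectorized weighted-least-squares
# solver.
.sym_from_upper <- function(vals, p) {
  A <- matrix(0, p, p)
  A[upper.tri(A, diag = TRUE)] <- vals
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}
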