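#' Construct an ATE estimate object
#'
#' @param tau finite numeric point estimate of the average treatment effect.
#' @param estimator which estimator produced it.
#' @param scale `"absolute"` (difference in expected outcomes) or `"percent"`.
#' @param n_used number of units entering the estimate.
#' @return An object of class `effect_estimate`.
#' @export
effect_estimate <- function(tau, estimator = c("OR", "IPW", "DR", "NAIVE"),
                            scale = c("absolute", "percent"), n_used = NA_integer_) {
  estimator <- match.arg(estimator)
  scale <- match.arg(scale)
  if (!is.finite(tau)) .stopf("ATE estimate must be finite")
  structure(list(tau = tau, estimator = estimator, scale = scale, n_used = n_used),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  unit <- if (x$scale == "percent") "%" else ""
  cat(sprintf("%s estimate of the ATE: %.4f%s (n = %s)\n",
              x$estimator, x$tau, unit, x$n_used))
  invisible(x)
}

#' Outcome-regression (plug-in) ATE estimator
#'
#' `tau = (1/n) sum_i [Psi^-1{m(1, x_i)} - Psi^-1{m(0, x_i)}]`, averaging the
#' difference of counterfactual predictions over the empirical covariate
#' distribution. Applied to a kappa-weighted fit this is the doubly robust
#' estimator.
#'
#' @param fit an [fit_outcome()] result (must have converged).
#' @param data the dataset whose covariate rows the predictions are averaged
#'   over.
#' @return An [effect_estimate()].
#' @export
ate_or <- function(fit, data) {
  stopifnot(inherits(fit, "or_fit"), inherits(data, "obs_dataset"))
  if (!isTRUE(fit$converged)) .stopf("outcome fit did not converge")
  mu1 <- predict_counterfactual(fit, data$X, 1)
  mu0 <- predict_counterfactual(fit, data$X, 0)
  est <- if (all(fit$weights_used == 1)) "OR" else "DR"
  effect_estimate(mean(mu1 - mu0), estimator = est, n_used = data$n)
}

#' Horvitz-Thompson inverse-propensity-weighted ATE estimator
#'
#' `tau = (1/n) sum_i [d_i y_i / ps_i - (1 - d_i) y_i / (1 - ps_i)]`.
#'
#' @param data an [observational_dataset()].
#' @param ps propensity scores strictly inside (0, 1).
#' @return An [effect_estimate()].
#' @export
ate_ipw <- function(data, ps) {
  stopifnot(inherits(data, "obs_dataset"))
  .check_prob_vector(ps, n = data$n)
  tau <- mean(data$d * data$y / ps - (1 - data$d) * data$y / (1 - ps))
  effect_estimate(tau, estimator = "IPW", n_used = data$n)
}

#' Naive unadjusted ATE estimator
#'
#' Difference in mean outcomes between treated and control units; no
#' confounding adjustment. Useful as the baseline the causal estimators are
#' compared against.
#'
#' @param data an [observational_dataset()].
#' @return An [effect_estimate()].
#' @export
ate_naive <- function(data) {
  stopifnot(inherits(data, "obs_dataset"))
  tau <- mean(data$y[data$d == 1]) - mean(data$y[data$d == 0])
  effect_estimate(tau, estimator = "NAIVE", n_used = data$n)
}

#' Doubly robust ATE estimator
#'
#' Fits the propensity model, forms inverse-propensity kappa weights, fits the
#' kappa-weighted outcome model, and plugs it into the outcome-regression
#' averaging formula. The result is consistent if either component model is
#' correctly specified.
#'
#' @param data an [observational_dataset()].
#' @param or_spec outcome [model_spec()]; defaults to identity link, all
#'   covariates linear.
#' @param ps_spec propensity [model_spec()]; defaults to a linear logit in all
#'   covariates. Ignored when `ps` is supplied.
#' @param ps optional fixed propensity vector (bypasses the propensity fit,
#'   e.g. known or externally estimated scores).
#' @param clip clipping constant applied to fitted propensities (see
#'   [fit_propensity()]).
#' @return An [effect_estimate()] with the component fits attached as
#'   attributes `ps_fit`, `or_fit` and `kappa`.
#' @export
ate_dr <- function(data, or_spec = NULL, ps_spec = NULL, ps = NULL, clip = 0.01) {
  stopifnot(inherits(data, "obs_dataset"))
  if (is.null(or_spec)) or_spec <- model_spec("identity", terms = colnames(data$X))
  ps_fit <- NULL
  if (is.null(ps)) {
    ps_fit <- fit_propensity(data, ps_spec, clip = clip)
    ps <- ps_fit$fitted_ps
  } else {
    .check_prob_vector(ps, n = data$n)
  }
  kappa <- kappa_weights(ps, data$d)
  or_fit <- fit_outcome(data, or_spec, weights = kappa)
  mu1 <- predict_counterfactual(or_fit, data$X, 1)
  mu0 <- predict_counterfactual(or_fit, data$X, 0)
  out <- effect_estimate(mean(mu1 - mu0), estimator = "DR", n_used = data$n)
  attr(out, "ps_fit") <- ps_fit
  attr(out, "or_fit") <- or_fit
  attr(out, "kappa") <- kappa
  out
}

#' Re-express an absolute ATE on the percent scale
#'
#' Reports `100 * tau / baseline`, where the baseline is the mean predicted
#' untreated outcome. This denominator is a reporting convention of this
#' package, stated explicitly because percent treatment effects have no
#' canonical denominator for differenced outcomes.
#'
#' @param estimate an [effect_estimate()] on the absolute scale.
#' @param baseline positive scalar, mean expected outcome in the absence of
#'   treatment.
#' @return An [effect_estimate()] with `scale = "percent"`.
#' @export
as_percent <- function(estimate, baseline) {
  stopifnot(inherits(estimate, "effect_estimate"), estimate$scale == "absolute")
  if (!is.finite(baseline) || baseline == 0) .stopf("baseline must be finite and non-zero")
  effect_estimate(100 * estimate$tau / baseline, estimator = estimate$estimator,
                  scale = "percent", n_used = estimate$n_used)
}

#' One-call ATE estimation pipeline
#'
#' Convenience wrapper used by the command-line interface: optional
#' nearest-neighbour matching, optional overlap trimming, then the requested
#' estimator on the retained sample. The sample size `n` entering the
#' estimator formulas is the post-matching, post-trimming size.
#'
#' @param data an [observational_dataset()].
#' @param estimator one of `"or"`, `"ipw"`, `"dr"`, `"naive"`.
#' @param or_spec,ps_spec component model specifications (defaults as in
#'   [ate_dr()]).
#' @param match logical: 1:1 nearest-neighbour propensity matching first?
#' @param trim optional `(lo, hi)` propensity bounds for overlap trimming.
#' @param clip propensity clipping constant.
#' @return A list with `estimate` (an [effect_estimate()]), `n_used` and
#'   `diagnostics`.
#' @export
estimate_ate <- function(data, estimator = c("dr", "or", "ipw", "naive"),
                         or_spec = NULL, ps_spec = NULL,
                         match = FALSE, trim = NULL, clip = 0.01) {
  estimator <- match.arg(estimator)
  diagnostics <- list(n_input = data$n)
  if (match || !is.null(trim)) {
    ps0 <- fit_propensity(data, ps_spec, clip = clip)$fitted_ps
    idx <- seq_len(data$n)
    if (match) {
      mr <- nearest_neighbor_match(ps0, data$d)
      idx <- mr$retained
      diagnostics$matching <- list(n_pairs = nrow(mr$matched_pairs),
                                   n_unmatched_treated = length(mr$unmatched_treated),
                                   mean_abs_ps_gap = mr$mean_abs_ps_gap)
    }
    if (!is.null(trim)) {
      sub <- subset_units(data, idx)
      oc <- check_overlap(sub, ps0[idx], bounds = trim)
      diagnostics$trimming <- list(dropped_treated = oc$n_dropped_treated,
                                   dropped_control = oc$n_dropped_control)
      idx <- idx[oc$retained]
    }
    data <- subset_units(data, idx)
  }
  est <- switch(estimator,
    naive = ate_naive(data),
    or = ate_or(fit_outcome(data, or_spec), data),
    ipw = ate_ipw(data, fit_propensity(data, ps_spec, clip = clip)$fitted_ps),
    dr = ate_dr(data, or_spec, ps_spec, clip = clip))
  list(estimate = est, n_used = data$n, diagnostics = diagnostics)
}
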