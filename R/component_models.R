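#' Specify a component regression model
#'
#' Describes either the propensity-score model pi(D | X; alpha) (logit link)
#' or the outcome-regression model Psi^-1{m(D, X; xi)}. Covariates enter
#' linearly through `terms` or as penalized cubic regression splines through
#' `smooth_terms` (basis dimension `basis_dim`, smoothing parameter chosen by
#' generalized cross-validation via \pkg{mgcv}).
#'
#' @param link link function Psi: one of `"identity"`, `"logit"`, `"log"`.
#' @param terms character vector of covariate names entering linearly.
#' @param smooth_terms character vector of covariate names entering as
#'   penalized splines.
#' @param basis_dim spline basis dimension (>= 3).
#' @param include_treatment should the treatment indicator enter the linear
#'   predictor? (Always `FALSE` for a propensity model.)
#' @param working_variance working conditional variance phi of the outcome
#'   given (D, X); a positive constant. It scales the estimating equations and
#'   cancels at their root, so the default 1 is used throughout.
#'
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(link = c("identity", "logit", "log"),
                       terms = character(), smooth_terms = character(),
                       basis_dim = 10, include_treatment = TRUE,
                       working_variance = 1) {
  link <- match.arg(link)
  if (basis_dim < 3) .stopf("smooth basis dimension must be >= 3")
  if (!identical(working_variance, "unit") &&
      (!is.numeric(working_variance) || working_variance <= 0)) {
    .stopf("working_variance must be a positive number or \"unit\"")
  }
  if (length(intersect(terms, smooth_terms)) > 0) {
    .stopf("a covariate cannot be both linear and smooth")
  }
  structure(list(link = link, terms = as.character(terms),
                 smooth_terms = as.character(smooth_terms),
                 basis_dim = basis_dim,
                 include_treatment = isTRUE(include_treatment),
                 working_variance = working_variance),
            class = "model_spec")
}

.has_smooths <- function(spec) length(spec$smooth_terms) > 0

.spec_family <- function(spec) {
  stats::gaussian(link = spec$link)
}

# Parametric design matrix: intercept, optional treatment column (named after
# the dataset's treatment variable, "d" by default), then linear covariates.
.design_matrix <- function(spec, X, d = NULL, treatment_name = "d") {
  n <- if (is.null(d)) nrow(X) else length(d)
  cols <- list("(Intercept)" = rep(1, n))
  if (spec$include_treatment) {
    if (is.null(d)) .stopf("treatment vector required by this model spec")
    cols[[treatment_name]] <- as.numeric(d)
  }
  missing_terms <- setdiff(spec$terms, colnames(X))
  if (length(missing_terms) > 0) {
    .stopf("schema error: covariate(s) %s not present in data",
           paste(missing_terms, collapse = ", "))
  }
  for (tm in spec$terms) cols[[tm]] <- X[, tm]
  do.call(cbind, cols)
}

.spec_formula <- function(spec, response, treatment_name = "d") {
  rhs <- character()
  if (spec$include_treatment) rhs <- treatment_name
  rhs <- c(rhs, spec$terms,
           sprintf("s(%s, k = %d, bs = \"cr\")", spec$smooth_terms, spec$basis_dim))
  if (length(rhs) == 0) rhs <- "1"
  stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

#' Fit the propensity-score model
#'
#' Maximizes the (optionally unit-weighted) binomial likelihood of treatment
#' given covariates under a logit link, by Newton-Raphson for parametric
#' specifications or by [mgcv::gam()] when the specification contains smooth
#' terms. Fitted probabilities are clipped to `[clip, 1 - clip]` before use in
#' inverse-propensity weights, which bounds the weights by `1/clip`.
#'
#' @param data an [observational_dataset()].
#' @param spec a [model_spec()] with `link = "logit"`. Defaults to a linear
#'   logit in all covariates.
#' @param unit_weights optional positive per-unit weights (e.g. Bayesian
#'   bootstrap weights).
#' @param clip clipping constant for the fitted probabilities (default 0.01;
#'   use 0 to disable).
#'
#' @return An object of class `ps_fit` with elements `alpha` (coefficients),
#'   `fitted_ps`, `spec`, `converged`.
#' @export
fit_propensity <- function(data, spec = NULL, unit_weights = NULL, clip = 0.01) {
  stopifnot(inherits(data, "obs_dataset"))
  if (is.null(spec)) spec <- model_spec("logit", terms = colnames(data$X),
                                        include_treatment = FALSE)
  if (spec$link != "logit") .stopf("propensity model requires a logit link")
  if (!is.null(unit_weights)) {
    if (length(unit_weights) != data$n || any(!is.finite(unit_weights)) ||
        any(unit_weights <= 0)) {
      .stopf("unit_weights must be strictly positive, finite, length n")
    }
  }
  if (.has_smooths(spec)) {
    df <- data.frame(.d = data$d, data$X, check.names = FALSE)
    df$.w <- if (is.null(unit_weights)) rep(1, data$n) else unit_weights
    form <- .spec_formula(spec_no_treat(spec), ".d")
    fit <- mgcv::gam(form, family = stats::binomial(), data = df,
                     weights = .w, method = "GCV.Cp")
    fitted <- as.numeric(fit$fitted.values)
    alpha <- stats::coef(fit)
    converged <- fit$converged
    gam_obj <- fit
  } else {
    Xmat <- .design_matrix(spec_no_treat(spec), data$X)
    fit <- .logit_fit(Xmat, data$d, w = unit_weights)
    if (!fit$converged) .stopf("propensity model did not converge after maximum iterations")
    fitted <- fit$fitted
    alpha <- stats::setNames(fit$coefficients, colnames(Xmat))
    converged <- fit$converged
    gam_obj <- NULL
    # perfect separation drives the binomial deviance to zero
    if (fit$deviance < 1e-6) {
      .stopf(paste("perfect separation: covariates fully predict treatment;",
                   "trim the sample or simplify the propensity model"))
    }
  }
  structure(list(alpha = alpha, fitted_ps = .clip_probs(fitted, clip),
                 spec = spec, converged = converged, clip = clip,
                 gam = gam_obj),
            class = "ps_fit")
}

spec_no_treat <- function(spec) { spec$include_treatment <- FALSE; spec }

#' @export
print.ps_fit <- function(x, ...) {
  cat("Propensity-score fit (logit)\n")
  print(round(x$alpha, 4))
  cat(sprintf("fitted range after clipping at %g: [%.4f, %.4f]\n",
              x$clip, min(x$fitted_ps), max(x$fitted_ps)))
  invisible(x)
}

#' Inverse-propensity (kappa) weights
#'
#' Computes `kappa_i = d_i / ps_i + (1 - d_i) / (1 - ps_i)`, the weight that
#' makes a (possibly misspecified) outcome-regression model consistent for the
#' ATE whenever the propensity model is correct.
#'
#' @param ps propensity scores strictly inside (0, 1) (clip first if needed).
#' @param d 0/1 treatment indicator of the same length.
#' @return Positive numeric weight vector.
#' @export
kappa_weights <- function(ps, d) {
  .check_prob_vector(ps, n = length(d))
  if (!all(d %in% c(0, 1))) .stopf("d must be a 0/1 vector")
  d / ps + (1 - d) / (1 - ps)
}

#' Bundle Bayesian-bootstrap and inverse-propensity weights
#'
#' @param w Bayesian-bootstrap weights, strictly positive and normalized so
#'   they sum to the number of units.
#' @param kappa inverse-propensity weights, strictly positive and finite.
#' @return A list of class `weight_set` with `w`, `kappa` and their
#'   elementwise product `combined`.
#' @export
weight_set <- function(w, kappa = rep(1, length(w))) {
  if (length(w) != length(kappa)) .stopf("w and kappa must have equal length")
  if (any(!is.finite(w)) || any(w <= 0)) .stopf("w must be strictly positive and finite")
  if (any(!is.finite(kappa)) || any(kappa <= 0)) .stopf("kappa must be strictly positive and finite")
  n <- length(w)
  if (abs(sum(w) - n) > 1e-6 * n) .stopf("w must be normalized to sum to n = %d", n)
  structure(list(w = w, kappa = kappa, combined = w * kappa), class = "weight_set")
}

#' Fit the (weighted) outcome-regression model
#'
#' Solves the weighted quasi-likelihood estimating equations
#' `sum_i weight_i (1/phi) de/dxi' (y_i - e(d_i, x_i; xi)) = 0`
#' for a Gaussian working model with link Psi. With the identity link this is
#' exactly weighted least squares; with other links it is solved by iteratively
#' reweighted least squares. Estimating-equation roots are invariant to
#' rescaling the weights or the working variance.
#'
#' @param data an [observational_dataset()].
#' @param spec a [model_spec()] for the outcome.
#' @param weights optional strictly positive unit weights (e.g. `w * kappa`);
#'   defaults to unit weights.
#'
#' @return An object of class `or_fit` with elements `xi` (coefficients),
#'   `spec`, `weights_used`, `converged`.
#' @export
fit_outcome <- function(data, spec = NULL, weights = NULL) {
  stopifnot(inherits(data, "obs_dataset"))
  if (is.null(spec)) spec <- model_spec("identity", terms = colnames(data$X))
  n <- data$n
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(!is.finite(weights)) || any(weights <= 0)) {
    .stopf("weights must be strictly positive, finite, length n")
  }
  if (.has_smooths(spec)) {
    df <- data.frame(.y = data$y, .d = data$d, data$X, check.names = FALSE)
    df$.w <- weights
    form <- .spec_formula(spec, ".y", treatment_name = ".d")
    fit <- mgcv::gam(form, family = .spec_family(spec), data = df,
                     weights = .w, method = "GCV.Cp")
    return(structure(list(xi = stats::coef(fit), spec = spec,
                          weights_used = weights, converged = fit$converged,
                          gam = fit, treatment_name = data$treatment_name),
                     class = "or_fit"))
  }
  Xmat <- .design_matrix(spec, data$X, data$d, treatment_name = data$treatment_name)
  if (spec$link == "identity") {
    qrX <- qr(Xmat * sqrt(weights))
    if (qrX$rank < ncol(Xmat)) .stopf("singular design: outcome design matrix is rank deficient")
    fit <- stats::lm.wfit(Xmat, data$y, weights)
    xi <- fit$coefficients
    converged <- TRUE
  } else {
    fam <- .spec_family(spec)
    mustart <- if (spec$link == "log") pmax(data$y, max(data$y) * 1e-3, 1e-3) else NULL
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(Xmat, data$y, weights = weights, family = fam,
                                      mustart = mustart,
                                      control = list(epsilon = 1e-8, maxit = 100))),
      error = function(e) .stopf("outcome model IRLS failed: %s", conditionMessage(e)))
    if (!fit$converged) .stopf("outcome model IRLS did not converge within 100 iterations")
    xi <- fit$coefficients
    converged <- fit$converged
  }
  if (anyNA(xi)) .stopf("singular design: outcome design matrix is rank deficient")
  structure(list(xi = stats::setNames(as.numeric(xi), colnames(Xmat)),
                 spec = spec, weights_used = weights, converged = converged,
                 gam = NULL, treatment_name = data$treatment_name),
            class = "or_fit")
}

#' @export
print.or_fit <- function(x, ...) {
  cat(sprintf("Outcome-regression fit (%s link)\n", x$spec$link))
  print(round(x$xi, 4))
  invisible(x)
}

#' Predict counterfactual mean outcomes
#'
#' Evaluates `Psi^-1{m(d, x_i; xi)}` for every covariate row with the
#' treatment indicator fixed at `d`.
#'
#' @param fit an [fit_outcome()] result.
#' @param X covariate matrix (or data frame) with the columns required by the
#'   fit's specification.
#' @param d scalar 0 or 1.
#' @return Numeric vector of predicted means, one per row of `X`.
#' @export
predict_counterfactual <- function(fit, X, d) {
  stopifnot(inherits(fit, "or_fit"), d %in% c(0, 1))
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.null(fit$gam)) {
    nd <- data.frame(X, check.names = FALSE)
    nd$.d <- d
    return(as.numeric(stats::predict(fit$gam, newdata = nd, type = "response")))
  }
  Xmat <- .design_matrix(fit$spec, X, rep(d, nrow(X)),
                         treatment_name = fit$treatment_name)
  eta <- unname(drop(Xmat %*% fit$xi))
  .spec_family(fit$spec)$linkinv(eta)
}

# Max-norm residual of the weighted estimating equations at coefficients xi;
# used to verify stored posterior draws.
estimating_equation_residual <- function(data, spec, weights, xi) {
  Xmat <- .design_matrix(spec, data$X, data$d, treatment_name = data$treatment_name)
  fam <- .spec_family(spec)
  eta <- drop(Xmat %*% xi)
  mu <- fam$linkinv(eta)
  dmu <- fam$mu.eta(eta)
  max(abs(crossprod(Xmat, weights * dmu * (data$y - mu))))
}
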