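test_that("outcome-regression ATE reduces to the treatment coefficient under identity link", {
  set.seed(201)
  dat <- generate_sim_dataset(dgp_params(n = 200))
  fit <- fit_outcome(dat)
  est <- ate_or(fit, dat)
  expect_equal(est$tau, unname(fit$xi["d"]), tolerance = 1e-12)
})

test_that("log-link OR averaging matches the hand-computed oracle", {
  # xi = (0, log 3, 1), covariate values {0, log 2}:
  # x = 0:    exp(log3) - exp(0)        = 3 - 1 = 2
  # x = log2: exp(log3 + log2) - exp(log2) = 6 - 2 = 4   -> mean 3
  fit <- manual_or_fit(c("(Intercept)" = 0, d = log(3), x = 1), link = "log")
  dat <- observational_dataset(c(1, 1), c(1, 0), cbind(x = c(0, log(2))))
  fit$weights_used <- rep(1, 2)
  expect_equal(ate_or(fit, dat)$tau, 3, tolerance = 1e-12)
})

test_that("naive estimator is the difference in arm means", {
  set.seed(202)
  y <- rnorm(40); d <- rep(c(1, 0), 20)
  dat <- observational_dataset(y, d, cbind(x = rnorm(40)))
  expect_equal(ate_naive(dat)$tau, mean(y[d == 1]) - mean(y[d == 0]))
  # an OR model without covariates reproduces it exactly
  fit <- fit_outcome(dat, model_spec("identity", terms = character()))
  expect_equal(ate_or(fit, dat)$tau, ate_naive(dat)$tau, tolerance = 1e-10)
})

test_that("IPW estimator follows the Horvitz-Thompson formula on printed toys", {
  dat <- observational_dataset(c(2, 4), c(1, 0), cbind(x = c(0, 0)))
  expect_equal(ate_ipw(dat, c(0.5, 0.5))$tau, -2)
  dat2 <- observational_dataset(rep(1, 4), c(1, 1, 0, 0), cbind(x = rep(0, 4)))
  expect_equal(ate_ipw(dat2, rep(0.5, 4))$tau, 0)
  expect_error(ate_ipw(dat, c(0, 0.5)), "strictly inside")
})

test_that("IPW with the true propensity is centered on the true ATE at large n", {
  set.seed(203)
  dat <- generate_sim_dataset(dgp_params(n = 1e5))
  true_ps <- plogis(2 + 0.2 * dat$X[, "x"])
  expect_equal(ate_ipw(dat, true_ps)$tau, 5, tolerance = 0.2)
})

test_that("OR and DR estimates are exactly shift-equivariant; balanced IPW too", {
  set.seed(204)
  dat <- generate_sim_dataset(dgp_params(n = 500))
  shifted <- observational_dataset(dat$y + 100, dat$d, dat$X)
  expect_equal(ate_or(fit_outcome(dat), dat)$tau,
               ate_or(fit_outcome(shifted), shifted)$tau, tolerance = 1e-8)
  ps <- runif(500, 0.2, 0.8)
  expect_equal(ate_dr(dat, ps = ps)$tau, ate_dr(shifted, ps = ps)$tau,
               tolerance = 1e-8)
  # Horvitz-Thompson IPW is shift-equivariant when the weights balance exactly
  yb <- rnorm(10); db <- rep(c(1, 0), 5)
  datb <- observational_dataset(yb, db, cbind(x = rep(0, 10)))
  datbs <- observational_dataset(yb + 100, db, cbind(x = rep(0, 10)))
  expect_equal(ate_ipw(datb, rep(0.5, 10))$tau, ate_ipw(datbs, rep(0.5, 10))$tau,
               tolerance = 1e-10)
})

test_that("a constant propensity of 0.5 makes DR coincide with unweighted OR", {
  set.seed(205)
  dat <- generate_sim_dataset(dgp_params(n = 400))
  dr <- ate_dr(dat, ps = rep(0.5, 400))
  or <- ate_or(fit_outcome(dat), dat)
  expect_equal(dr$tau, or$tau, tolerance = 1e-10)
})

test_that("weighting does not break a correctly specified outcome model", {
  set.seed(206)
  dat <- generate_sim_dataset(dgp_params(n = 1e4))
  ps <- runif(1e4, 0.1, 0.9)  # arbitrary fixed propensity, wrong on purpose
  dr <- ate_dr(dat, ps = ps)
  or <- ate_or(fit_outcome(dat), dat)
  # both estimate tau = 5; the kappa weighting only perturbs efficiency
  se <- sqrt(5 / (1e4 * 0.12))  # outcome noise / effective treated-arm size
  expect_lt(abs(dr$tau - or$tau), 2 * se)
  expect_equal(dr$tau, 5, tolerance = 0.2)
})

test_that("percent-scale reporting divides by the stated baseline", {
  est <- effect_estimate(-1.5, "DR")
  pct <- as_percent(est, baseline = 10)
  expect_equal(pct$tau, -15)
  expect_equal(pct$scale, "percent")
  expect_error(as_percent(pct, 10), "absolute")
})

test_that("the pipeline wrapper matches, trims and reports diagnostics", {
  set.seed(207)
  sites <- generate_sites(synth_config(n_treated = 150, n_control_reservoir = 900))
  dat <- sites_to_dataset(sites)
  res <- suppressWarnings(estimate_ate(dat, "dr", match = TRUE, trim = c(0.01, 0.99)))
  expect_s3_class(res$estimate, "effect_estimate")
  expect_lt(res$n_used, dat$n)
  expect_true(res$diagnostics$matching$n_pairs > 0)
})
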