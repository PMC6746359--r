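test_that("kappa weights follow the inverse-propensity formula", {
  expect_equal(kappa_weights(0.5, 1), 2)
  expect_equal(kappa_weights(0.2, 0), 1.25)
  expect_equal(kappa_weights(0.98, 1), 1 / 0.98, tolerance = 1e-12)
  expect_error(kappa_weights(c(0, 0.5), c(1, 0)), "strictly inside")
  expect_error(kappa_weights(c(0.5, 1), c(1, 0)), "strictly inside")
})

test_that("propensity fit recovers the null model when treatment ignores X", {
  set.seed(101)
  n <- 20000
  x <- rnorm(n)
  d <- rbinom(n, 1, 0.4)
  dat <- observational_dataset(rnorm(n), d, cbind(x = x))
  fit <- fit_propensity(dat)
  expect_true(fit$converged)
  expect_equal(unname(fit$alpha["x"]), 0, tolerance = 0.05)
  expect_equal(unname(fit$alpha["(Intercept)"]), qlogis(mean(d)), tolerance = 0.05)
  expect_true(all(fit$fitted_ps > 0 & fit$fitted_ps < 1))
})

test_that("propensity fit recovers the assignment coefficients at large n", {
  set.seed(102)
  dat <- generate_sim_dataset(dgp_params(n = 1e5))
  fit <- fit_propensity(dat, model_spec("logit", terms = "x", include_treatment = FALSE))
  expect_equal(unname(fit$alpha), c(2, 0.2), tolerance = 0.05)
})

test_that("perfect separation is reported with advice rather than silently fitted", {
  dat <- observational_dataset(rnorm(6), c(1, 1, 1, 0, 0, 0),
                               cbind(x = c(5, 6, 7, -5, -6, -7)))
  expect_error(fit_propensity(dat, clip = 0), "separation")
})

test_that("identity-link outcome fit interpolates an exactly linear response", {
  dat <- toy_linear_dataset()
  fit <- fit_outcome(dat)
  expect_equal(unname(fit$xi), c(1, 2, 3), tolerance = 1e-10)
})

test_that("estimating-equation roots are invariant to rescaling the weights", {
  set.seed(103)
  dat <- generate_sim_dataset(dgp_params(n = 300))
  f1 <- fit_outcome(dat)
  f2 <- fit_outcome(dat, weights = rep(7.3, 300))
  expect_equal(f1$xi, f2$xi, tolerance = 1e-10)
})

test_that("weighted identity-link fits match the closed-form WLS oracle", {
  set.seed(104)
  for (rep in 1:5) {
    dat <- generate_sim_dataset(dgp_params(n = 120))
    w <- rexp(120) + 0.1
    fit <- fit_outcome(dat, weights = w)
    oracle <- wls_oracle(cbind(1, dat$d, dat$X[, "x"]), dat$y, w)
    expect_equal(unname(fit$xi), oracle, tolerance = 1e-8)
  }
})

test_that("rank-deficient outcome designs raise a singular-design error", {
  d <- c(1, 0, 1, 0)
  X <- cbind(x = c(1, 2, 3, 4), x2 = 2 * c(1, 2, 3, 4))
  dat <- observational_dataset(rnorm(4), d, X)
  expect_error(fit_outcome(dat, model_spec("identity", terms = c("x", "x2"))),
               "singular")
})

test_that("counterfactual predictions evaluate the inverse-link mean", {
  fit <- manual_or_fit(c("(Intercept)" = 1, d = 2, x = 3))
  expect_equal(predict_counterfactual(fit, cbind(x = 4), 1), 15)
  X <- cbind(x = c(-2, 0, 4, 17))
  expect_equal(predict_counterfactual(fit, X, 1) - predict_counterfactual(fit, X, 0),
               rep(2, 4))
  logfit <- manual_or_fit(c("(Intercept)" = 0, d = log(2), x = 0), link = "log")
  expect_equal(predict_counterfactual(logfit, cbind(x = c(-1, 3)), 1), c(2, 2))
  expect_error(predict_counterfactual(fit, cbind(z = 1:2), 1), "schema")
})

test_that("kappa weights from a calibrated propensity balance both arms' mass", {
  set.seed(105)
  dat <- generate_sim_dataset(dgp_params(n = 1e4))
  ps <- fit_propensity(dat, model_spec("logit", terms = "x",
                                       include_treatment = FALSE))$fitted_ps
  k <- kappa_weights(ps, dat$d)
  # Horvitz-Thompson mass balance: each arm's kappa mass estimates n
  expect_equal(sum(k[dat$d == 1]), dat$n, tolerance = 0.05 * dat$n)
  expect_equal(sum(k[dat$d == 0]), dat$n, tolerance = 0.05 * dat$n)
})

test_that("kappa weighting from a correct propensity corrects omitted-covariate bias", {
  set.seed(106)
  reps <- 50
  bias_weighted <- bias_unweighted <- numeric(reps)
  spec_noX <- model_spec("identity", terms = character())
  for (r in seq_len(reps)) {
    dat <- generate_sim_dataset(dgp_params(n = 1000))
    ps <- fit_propensity(dat, model_spec("logit", terms = "x",
                                         include_treatment = FALSE))$fitted_ps
    k <- kappa_weights(ps, dat$d)
    bias_weighted[r] <- fit_outcome(dat, spec_noX, weights = k)$xi["d"] - 5
    bias_unweighted[r] <- fit_outcome(dat, spec_noX)$xi["d"] - 5
  }
  diff <- abs(mean(bias_unweighted)) - abs(mean(bias_weighted))
  se <- sqrt(var(bias_unweighted) / reps + var(bias_weighted) / reps)
  expect_gt(diff, 2 * se)
})

test_that("kappa-weighted fit with the true propensity removes confounding at large n", {
  set.seed(107)
  dat <- generate_sim_dataset(dgp_params(n = 1e5))
  true_ps <- plogis(2 + 0.2 * dat$X[, "x"])
  k <- kappa_weights(true_ps, dat$d)
  fit <- fit_outcome(dat, model_spec("identity", terms = character()), weights = k)
  expect_equal(unname(fit$xi["d"]), 5, tolerance = 0.15)
})

test_that("smooth-term specifications fit via penalized splines and predict", {
  set.seed(108)
  n <- 500
  x <- runif(n, -3, 3)
  d <- rbinom(n, 1, plogis(sin(x)))
  y <- 2 * d + cos(x) + rnorm(n, 0, 0.3)
  dat <- observational_dataset(y, d, cbind(x = x))
  psf <- fit_propensity(dat, model_spec("logit", smooth_terms = "x",
                                        include_treatment = FALSE))
  expect_true(all(psf$fitted_ps > 0 & psf$fitted_ps < 1))
  orf <- fit_outcome(dat, model_spec("identity", smooth_terms = "x"))
  mu1 <- predict_counterfactual(orf, dat$X, 1)
  mu0 <- predict_counterfactual(orf, dat$X, 0)
  expect_equal(mean(mu1 - mu0), 2, tolerance = 0.15)
})
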