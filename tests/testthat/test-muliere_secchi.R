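# A cheap empirical posterior reused across the Muliere-Secchi tests.
make_pn <- function(n = 300, L = 200, seed = 500) {
  withr::with_seed(seed, {
    dat <- generate_sim_dataset(dgp_params(n = n))
    list(pn = empirical_posterior(dat, L = L), dat = dat)
  })
}

test_that("zero faith makes the mixture a pure resample of the empirical posterior", {
  env <- make_pn()
  set.seed(501)
  sup <- mix_prior(env$pn, prior_spec(5, 10, faith = 0), m = 500)
  expect_false(any(attr(sup, "from_prior")))
  # every support row is one of the posterior rows
  keys <- apply(env$pn$draws, 1, paste, collapse = "|")
  expect_true(all(apply(sup, 1, paste, collapse = "|") %in% keys))
})

test_that("overwhelming faith reproduces the prior marginal on the target coordinate", {
  env <- make_pn()
  set.seed(502)
  sup <- mix_prior(env$pn, prior_spec(5, 10, faith = 1e9), m = 1e4)
  expect_gt(mean(attr(sup, "from_prior")), 0.999)
  ks <- suppressWarnings(ks.test(sup[, "d"], "pnorm", 5, 10))
  expect_gt(ks$p.value, 0.01)
})

test_that("faith equal to L mixes prior and data in equal proportion", {
  env <- make_pn()
  set.seed(503)
  sup <- mix_prior(env$pn, prior_spec(5, 10, faith = env$pn$L), m = 1e4)
  frac <- mean(attr(sup, "from_prior"))
  expect_equal(frac, 0.5, tolerance = 3 * sqrt(0.25 / 1e4) / 0.5)
})

test_that("gamma weights have mean (L + k) / m", {
  set.seed(504)
  m <- 100; L <- 200; k <- 1
  sup <- matrix(0, m, 2)
  v <- unlist(lapply(1:1000, function(i) gamma_reweight(sup, L, k)$gamma_weights))
  expect_equal(mean(v), (L + k) / m, tolerance = 0.01 * (L + k) / m)
})

test_that("a single support point gives a point-mass posterior", {
  set.seed(505)
  sup <- matrix(c(1, 2, 3), 1, 3, dimnames = list(NULL, c("(Intercept)", "d", "x")))
  pm <- gamma_reweight(sup, L = 200, k = 1)
  expect_equal(nrow(pm$resampled), 1)
  expect_equal(unname(pm$resampled[1, ]), c(1, 2, 3))
  dat <- withr::with_seed(1, generate_sim_dataset(dgp_params(n = 50)))
  post <- posterior_predictive_ate(pm, dat, model_spec("identity", terms = "x"), M = 100)
  expect_true(all(post$draws == 2))
})

test_that("small faith leaves the treatment-coordinate law close to plain resampling", {
  # the gamma-reweighted posterior concentrates on few atoms within a single
  # realization (it approximates a Dirichlet process path of total mass
  # L + k), so the comparison with plain resampling is over the marginal law:
  # draws pooled over independent reweighting realizations
  env <- make_pn()
  set.seed(506)
  pooled <- unlist(lapply(1:500, function(i) {
    sup <- mix_prior(env$pn, prior_spec(5, 10, faith = 1), m = 200)
    pm <- gamma_reweight(sup, L = env$pn$L, k = 1)
    pm$resampled[sample.int(200, 20), "d"]
  }))
  direct <- env$pn$draws[sample.int(env$pn$L, 1e4, replace = TRUE), "d"]
  ks <- suppressWarnings(ks.test(pooled, direct))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("identity-link predictive draws equal the drawn treatment coefficients", {
  env <- make_pn()
  set.seed(507)
  sup <- mix_prior(env$pn, prior_spec(5, 10, faith = 1), m = 200)
  pm <- gamma_reweight(sup, L = 200, k = 1)
  post <- posterior_predictive_ate(pm, env$dat, model_spec("identity", terms = "x"),
                                   M = 500)
  expect_true(all(post$draws %in% sup[, "d"]))
  expect_equal(length(post$draws), 500)
})

test_that("log-link point-mass posterior reproduces the hand-computed ATE", {
  sup <- matrix(c(0, log(3), 1), 1, 3,
                dimnames = list(NULL, c("(Intercept)", "d", "x")))
  pm <- gamma_reweight(sup, L = 10, k = 0)
  # constant covariate pool: every resampled average is exactly
  # exp(log3 + log2) - exp(log2) = 4
  datc <- observational_dataset(c(1, 1), c(1, 0), cbind(x = c(log(2), log(2))))
  set.seed(508)
  postc <- posterior_predictive_ate(pm, datc, model_spec("log", terms = "x"),
                                    V = 50, M = 100)
  expect_equal(unname(postc$draws), rep(4, 100), tolerance = 1e-12)
  # two-value pool {0, log 2}: per-row effects are 2 and 4, so the posterior
  # mean over covariate resamples is the hand-computed ATE of 3
  dat <- observational_dataset(c(1, 1), c(1, 0), cbind(x = c(0, log(2))))
  post <- posterior_predictive_ate(pm, dat, model_spec("log", terms = "x"),
                                   V = 400, M = 400)
  expect_true(all(post$draws >= 2 & post$draws <= 4))
  expect_equal(post$summaries$mean, 3, tolerance = 0.05)
})

test_that("with zero faith the ATE posterior matches resampled empirical draws", {
  # marginal comparison: pool predictive draws over independent mixture and
  # reweighting realizations (see the small-faith test above)
  env <- make_pn()
  set.seed(509)
  spec <- model_spec("identity", terms = "x")
  pooled <- unlist(lapply(1:250, function(i) {
    sup <- mix_prior(env$pn, prior_spec(5, 10, faith = 0), m = env$pn$L)
    pm <- gamma_reweight(sup, L = env$pn$L, k = 0)
    posterior_predictive_ate(pm, env$dat, spec, M = 20)$draws
  }))
  direct <- env$pn$draws[sample.int(env$pn$L, 5000, replace = TRUE), "d"]
  ks <- suppressWarnings(ks.test(pooled, direct))
  expect_gt(ks$p.value, 0.01)
})

test_that("posterior summaries are pure functions of the draws", {
  set.seed(510)
  draws <- rnorm(2000, -1, 0.5)
  s1 <- summarize_ate_draws(draws)
  s2 <- summarize_ate_draws(draws)
  expect_identical(s1, s2)
  expect_equal(s1$mean, mean(draws))
  expect_equal(s1$sd, sd(draws))
  expect_equal(c(s1$ci_lower, s1$ci_upper),
               unname(quantile(draws, c(0.025, 0.975))))
})

test_that("prior and mixture arguments are validated", {
  expect_error(prior_spec(scale = -1), "positive")
  expect_error(prior_spec(faith = -2), ">= 0")
  env <- make_pn()
  expect_error(mix_prior(env$pn, prior_spec(coordinate = "nope")), "not found")
})
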