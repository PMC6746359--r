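#' Configuration of the synthetic site-panel generator
#'
#' Generates road-network sites with the structure of a speed-camera
#' evaluation: a 3-year pre-treatment period whose personal-injury collision
#' (PIC) count doubles as the collision history used for treatment selection,
#' a 3-year post-treatment period, and the covariates that drive both
#' collision risk and camera assignment (traffic flow, road type, speed limit,
#' minor junctions, site length). Treatment assignment follows the UK site
#' selection guidelines as soft thresholds: the assignment probability jumps
#' when the site history reaches `pic_threshold` PICs per km and
#' `fsc_threshold` fatal-or-serious collisions (FSCs) per km over the three
#' pre years, with residual noise because sites failing the criteria are still
#' occasionally treated. Because selection conditions on the realized pre
#' -period counts, a naive before/after comparison at treated sites is
#' contaminated by regression to the mean; the covariates recorded per site
#' are sufficient to remove that confounding.
#'
#' Post-period counts are Poisson around a latent site risk that includes a
#' time-invariant site effect; at treated sites the expected post count is
#' multiplied by `true_effect` (1 = no effect, 0.85 = a 15% reduction).
#'
#' @param n_treated target expected number of treated sites.
#' @param n_control_reservoir target expected number of untreated reservoir
#'   sites (default keeps the roughly 6:1 reservoir-to-treated ratio typical
#'   of camera evaluations).
#' @param true_effect multiplicative change in expected post-period collision
#'   counts at treated sites.
#' @param base_rate baseline PIC rate per km-year at the median site.
#' @param rate_sd standard deviation of the lognormal site effect on the
#'   collision rate (the time-invariant heterogeneity differencing removes).
#' @param confound_strength log-odds jump in assignment probability at the
#'   PIC-history threshold (the FSC threshold contributes 60% of this).
#' @param fsc_frac probability that a PIC is fatal or serious.
#' @param pic_threshold,fsc_threshold selection guideline thresholds, per km
#'   over the 3-year history.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_treated = 700, n_control_reservoir = 4200,
                         true_effect = 0.85, base_rate = 1.2, rate_sd = 0.45,
                         confound_strength = 2.5, fsc_frac = 0.35,
                         pic_threshold = 8, fsc_threshold = 4) {
  if (n_treated < 1 || n_control_reservoir < 1) {
    .stopf("n_treated and n_control_reservoir must be positive")
  }
  if (n_control_reservoir < n_treated) {
    .stopf("infeasible config: control reservoir must exceed the treated count")
  }
  if (true_effect <= 0) .stopf("true_effect must be positive (multiplicative)")
  if (base_rate <= 0 || rate_sd < 0 || fsc_frac < 0 || fsc_frac > 1) {
    .stopf("invalid rate parameters")
  }
  structure(list(n_treated = n_treated, n_control_reservoir = n_control_reservoir,
                 true_effect = true_effect, base_rate = base_rate,
                 rate_sd = rate_sd, confound_strength = confound_strength,
                 fsc_frac = fsc_frac, pic_threshold = pic_threshold,
                 fsc_threshold = fsc_threshold),
            class = "synth_config")
}

#' Generate a synthetic site panel
#'
#' @param config a [synth_config()].
#' @return A data frame with one row per site: `site_id`, `length_km`,
#'   `pic3`, `fsc3` (3-year collision history), `aadf`, `road_type`,
#'   `speed_limit`, `minor_junctions`, `treated`, `pre_count`, `post_count`.
#'   The latent expected 3-year counts and the embedded effect are attached as
#'   attributes `latent_mu3` and `true_effect` so recovery can be checked
#'   against the generator's truth.
#' @export
generate_sites <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  N <- config$n_treated + config$n_control_reservoir
  length_km <- stats::runif(N, 0.4, 1.5)
  road_type <- sample(c("A", "B", "C"), N, replace = TRUE, prob = c(0.45, 0.35, 0.20))
  speed_limit <- sample(c(30, 40), N, replace = TRUE, prob = c(0.7, 0.3))
  aadf <- stats::rlnorm(N, meanlog = 9, sdlog = 0.6)
  minor_junctions <- stats::rpois(N, 2 * length_km)
  site_effect <- stats::rnorm(N, 0, config$rate_sd)
  log_rate <- log(config$base_rate) +
    0.35 * (log(aadf) - 9) +
    c(A = 0.25, B = 0.05, C = -0.15)[road_type] +
    0.10 * (speed_limit == 30) +
    0.04 * minor_junctions +
    site_effect
  mu3 <- 3 * length_km * exp(log_rate)  # expected PICs over a 3-year period
  pic3 <- stats::rpois(N, mu3)
  fsc3 <- stats::rbinom(N, pic3, config$fsc_frac)
  pic_rate <- pic3 / length_km
  fsc_rate <- fsc3 / length_km
  z_aadf <- (log(aadf) - 9) / 0.6
  sel <- config$confound_strength * (pic_rate >= config$pic_threshold) +
    0.6 * config$confound_strength * (fsc_rate >= config$fsc_threshold) +
    0.15 * z_aadf + 0.10 * (speed_limit == 30)
  # calibrate the assignment intercept so the expected treated count matches
  target <- config$n_treated / N
  c0 <- stats::uniroot(function(b) mean(.expit(b + sel)) - target,
                       interval = c(-30, 30))$root
  treated <- stats::rbinom(N, 1, .expit(c0 + sel))
  if (sum(treated) == 0) treated[which.max(sel)] <- 1L
  if (sum(treated) == N) treated[which.min(sel)] <- 0L
  pre_count <- pic3  # the selection history is the pre period
  post_count <- stats::rpois(N, mu3 * config$true_effect^treated)
  sites <- data.frame(site_id = seq_len(N), length_km = length_km,
                      pic3 = pic3, fsc3 = fsc3, aadf = aadf,
                      road_type = road_type, speed_limit = speed_limit,
                      minor_junctions = minor_junctions, treated = treated,
                      pre_count = pre_count, post_count = post_count)
  attr(sites, "latent_mu3") <- mu3
  attr(sites, "true_effect") <- config$true_effect
  attr(sites, "config") <- config
  sites
}

#' Differenced before/after outcome
#'
#' `y_i = post_i - pre_i`. Differencing removes any site-constant additive
#' effect, which is how the analysis model accommodates time-invariant site
#' heterogeneity without random effects.
#'
#' @param pre_count,post_count equal-length count vectors.
#' @return Numeric vector of differences.
#' @export
difference_outcome <- function(pre_count, post_count) {
  if (length(pre_count) != length(post_count)) .stopf("pre and post must have equal length")
  as.numeric(post_count) - as.numeric(pre_count)
}

#' Convert a site panel to an observational dataset
#'
#' Builds the differenced outcome and the analysis covariates: collision
#' history rates and their guideline-threshold indicators, log traffic flow,
#' site length, road-type and speed-limit dummies, and minor junction count.
#'
#' @param sites a data frame from [generate_sites()] (or with the same
#'   columns).
#' @param pic_threshold,fsc_threshold thresholds used for the indicator
#'   covariates.
#' @return An [observational_dataset()] carrying over the `latent_mu3` and
#'   `true_effect` attributes when present.
#' @export
sites_to_dataset <- function(sites, pic_threshold = 8, fsc_threshold = 4) {
  pic_rate <- sites$pic3 / sites$length_km
  fsc_rate <- sites$fsc3 / sites$length_km
  X <- cbind(pic_rate = pic_rate,
             fsc_rate = fsc_rate,
             over_pic = as.numeric(pic_rate >= pic_threshold),
             over_fsc = as.numeric(fsc_rate >= fsc_threshold),
             log_aadf = log(sites$aadf),
             length_km = sites$length_km,
             speed40 = as.numeric(sites$speed_limit == 40),
             road_B = as.numeric(sites$road_type == "B"),
             road_C = as.numeric(sites$road_type == "C"),
             minor_junctions = sites$minor_junctions)
  out <- observational_dataset(difference_outcome(sites$pre_count, sites$post_count),
                               sites$treated, X)
  attr(out, "latent_mu3") <- attr(sites, "latent_mu3")
  attr(out, "true_effect") <- attr(sites, "true_effect")
  out
}

#' Recover the embedded treatment effect from a site panel
#'
#' Runs the full analysis pipeline on a synthetic panel: 1:1 nearest-neighbour
#' propensity matching, overlap trimming, propensity refit on the retained
#' sample, inverse-propensity kappa weights, Bayesian-bootstrap posterior of
#' the kappa-weighted Gaussian outcome model on the differenced response, and
#' the Muliere-Secchi posterior predictive distribution of the absolute ATE
#' (change in 3-year collision count per site).
#'
#' @param sites a data frame from [generate_sites()].
#' @param or_terms covariates of the outcome model (default: all).
#' @param ps_terms covariates of the propensity model (default: all).
#' @param L,M,V approximate Bayesian sample sizes (see
#'   [empirical_posterior()], [posterior_predictive_ate()]).
#' @param prior a [prior_spec()] on the treatment coefficient; default is a
#'   Normal(0, sd 5) with faith `k = 1`, weakly informative on the scale of
#'   plausible per-site changes in 3-year collision counts. Note that in the
#'   mixture-resampling scheme the prior keeps probability mass `k / (k + L)`
#'   in the posterior regardless of the data, so a prior with an absurdly
#'   large scale inflates the posterior spread rather than washing out.
#' @param bounds overlap-trimming propensity bounds after matching.
#' @param clip propensity clipping constant.
#' @return An `ate_posterior` (see [posterior_predictive_ate()]) with
#'   attributes `implied_ate` (the generator-implied absolute ATE over the
#'   analysis sample, when the panel carries its latent risks), `n_used` and
#'   `baseline_post` (mean expected untreated post count over the analysis
#'   sample, the denominator for percent reporting).
#' @export
recover_effect <- function(sites, or_terms = NULL, ps_terms = NULL,
                           L = 200, M = 1000, V = NULL,
                           prior = prior_spec(0, 5, 1, "d"),
                           bounds = c(0.01, 0.99), clip = 0.01) {
  data <- sites_to_dataset(sites)
  if (is.null(or_terms)) or_terms <- colnames(data$X)
  if (is.null(ps_terms)) ps_terms <- colnames(data$X)
  ps_spec <- model_spec("logit", terms = ps_terms, include_treatment = FALSE)
  ps0 <- fit_propensity(data, ps_spec, clip = clip)
  mr <- suppressWarnings(nearest_neighbor_match(ps0$fitted_ps, data$d))
  idx <- mr$retained
  oc <- check_overlap(subset_units(data, idx), ps0$fitted_ps[idx], bounds = bounds)
  idx <- idx[oc$retained]
  sub <- subset_units(data, idx)
  ps1 <- fit_propensity(sub, ps_spec, clip = clip)
  kappa <- kappa_weights(ps1$fitted_ps, sub$d)
  or_spec <- model_spec("identity", terms = or_terms)
  pn <- empirical_posterior(sub, or_spec, kappa = kappa, L = L)
  support <- mix_prior(pn, prior, m = L)
  pm <- gamma_reweight(support, L = L, k = prior$faith)
  post <- posterior_predictive_ate(pm, sub, or_spec, V = V, M = M)
  mu3 <- attr(sites, "latent_mu3")
  te <- attr(sites, "true_effect")
  if (!is.null(mu3) && !is.null(te)) {
    attr(post, "implied_ate") <- mean(mu3[idx] * (te - 1))
    attr(post, "baseline_post") <- mean(mu3[idx])
  }
  attr(post, "n_used") <- sub$n
  post
}
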