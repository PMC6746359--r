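# bayesdr

Approximate Bayesian doubly robust (DR) estimation of average treatment
effects (ATE) for binary interventions in observational data, built for
road-safety evaluation problems — does installing a speed camera reduce
collisions at a site? — where treatment is assigned by formal, history-based
criteria and regression to the mean contaminates naive before/after
comparisons.

## What it computes

For units $z_i = (y_i, d_i, x_i)$ under strong ignorability, the package
estimates $\tau = E[Y(1)] - E[Y(0)]$ by:

* **OR**: outcome regression $\Psi^{-1}\{m(D,X;\xi)\}$, averaging
  counterfactual prediction differences;
* **IPW**: the Horvitz–Thompson estimator
  $\frac1n\sum_i [d_i y_i/\hat\pi_i - (1-d_i)y_i/(1-\hat\pi_i)]$ with a
  logistic propensity model $\hat\pi$;
* **DR**: the OR model refitted with inverse-propensity weights
  $\kappa_i = d_i/\hat\pi_i + (1-d_i)/(1-\hat\pi_i)$ — consistent if *either*
  component model is correct.

Because DR estimators are defined by estimating equations rather than a
likelihood, posterior inference uses the Bayesian bootstrap: the weighted
estimating equations are re-solved under Dirichlet observation weights
($L$ draws of standardized exponentials), prior information on the treatment
coefficient enters through Muliere–Secchi mixture resampling (prior mass
$k/(k+L)$), and the posterior predictive distribution of the ATE is built by
resampling covariates and drawing coefficients from the mixed posterior. See
`vignettes/approximate-bayesian-dr.Rmd` for the full method account.

The package also ships a Monte Carlo misspecification study of the seven
estimator configurations (correct/incorrect OR and propensity models) and a
synthetic generator of speed-camera-style site panels — collision histories,
threshold-based assignment, before/after Poisson counts with an embedded
multiplicative effect — so the whole matched, differenced, weighted pipeline
is testable against a known truth.

## Worked example

Generate a synthetic panel of 4900 sites with a 15% embedded collision
reduction at treated sites (`true_effect = 0.85`), then compare the naive
before/after contrast with the causal pipeline:

```r
library(bayesdr)
set.seed(42)
sites <- generate_sites(synth_config(true_effect = 0.85))
dat <- sites_to_dataset(sites)
dat
#> Observational dataset: 4900 units (704 treated, 4196 control), 10 covariate(s)

ate_naive(dat)
#> NAIVE estimate of the ATE: -2.6645 (n = 4900)

post <- recover_effect(sites)   # match -> trim -> PS -> kappa-weighted OR -> posterior
post
#> ATE posterior predictive (1000 draws): mean -1.0260, sd 0.1715, 95% CI [-1.3854, -0.6396]
attr(post, "implied_ate")       # generator's truth on the analysis sample
#> [1] -1.112
```

The naive contrast (−2.66 collisions per site over three years) overstates
the benefit by more than a factor two — sites were selected *because* their
recent history was bad, so they regress toward the mean regardless of
treatment. The DR posterior mean (−1.03) recovers the embedded truth (−1.11)
within one posterior standard deviation, and the 95% credible interval
excludes zero. On the percent scale (relative to the expected untreated
post-period count) the estimate is −13.8%, against the embedded −15%.

The misspecification study (here a 50-replication smoke run; the full study
uses 1000):

```r
set.seed(7)
reproduce_table1(n_runs = 50, L = 100, M = 500)
#>  scenario    avg_est      emp_var          mse n_runs
#>      BOR1   5.023147 5.714386e-02 5.653677e-02     50
#>      BOR2   5.360903 7.091825e-02 1.997511e-01     50
#>       PS1   4.979278 1.518195e-01 1.492126e-01     50
#>       PS2 254.685914 6.457294e+04 1.256245e+05     50
#>      BDR1   5.007629 9.993425e-02 9.799378e-02     50
#>      BDR2   4.850368 1.143127e+00 1.142655e+00     50
#>      BDR3   5.409025 1.398983e+00 1.538305e+00     50
```

The true ATE is 5. Scenarios with at least one correct component model
(BOR1, PS1, BDR1, BDR2) center on it; omitting the confounder from the
outcome model without a correct propensity (BOR2, BDR3) biases the estimate
up to ≈5.35–5.45; a randomly generated propensity (PS2) makes inverse
weighting explode.

## Command line

A thin front end over the same functions lives at `inst/cli/bayesdr`:

```sh
bayesdr estimate --data analysis.csv --estimator dr --match --trim 0.01,0.99 \
    --outcome y --treatment d --covariates pic_rate,fsc_rate,log_aadf
bayesdr simulate-table1 --runs 200 --seed 1 --out table1.csv
bayesdr synth-sites --seed 1 --out sites.csv
```
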