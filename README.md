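# mixds: finite mixture detection functions for distance sampling

Distance sampling estimates the size of a wildlife population from the
distances at which animals are detected from surveyed lines or points.
Detection is certain on the transect itself and decays with distance; the
decay is described by a *detection function* `g(y, z)` with `g(0, z) = 1`,
estimated from the observed distances and then inverted into an abundance
estimate. Good detection-function models should be flexible, efficient in
parameters, flat at zero distance, and monotone non-increasing. The
standard "key function plus series adjustment" (K+A) family meets the first
three criteria but can violate the fourth: adjustment series can put bumps
or negative excursions into the fitted function, and with covariates in
the model there is no practical way to constrain them.

`mixds` fits detection functions built as **finite mixtures of half-normal
components**,

    g(y, z) = sum_j phi_j exp( -y^2 / (2 sigma_j(z)^2) ),   sum_j phi_j = 1,
    sigma_ij = exp( beta_0j + sum_k beta_k z_ik ),

which are monotone non-increasing, bounded in (0, 1], and equal to 1 at
zero distance *for every parameter value* — no constrained optimisation is
needed. Covariates act log-linearly on all component scales with shared
slopes. The package is aimed at distance-sampling analysts who want this
family alongside (and compared against) the conventional K+A models.

What it provides:

* line-, point-transect and binned-multinomial maximum likelihood, with
  left truncation, analytic gradients and closed-form effective strip
  width / effective detection area for half-normal mixtures;
* the K+A baseline family (half-normal / hazard-rate / uniform keys with
  cosine, simple-polynomial or Hermite adjustments), fitted with
  monotonicity constraints on a 20-point distance grid via an augmented
  Lagrangian, plus a monotonicity diagnostic (`check_monotone()`);
* Horvitz–Thompson abundance (`N_hat = (A/a) * sum 1/p_i`) and average
  detectability `P_a = n / N_hat`, with delta-method and encounter-rate
  variance components;
* AIC model selection (`fit_candidates()` + `select_aic()`) with forward
  selection over adjustment terms, Kolmogorov–Smirnov goodness of fit and
  Q–Q diagnostics;
* a simulation harness (`make_scenarios()`, `run_study()`) with scenario
  groups covering spiked, wide-shouldered, covariate-heterogeneous and
  non-half-normal detection processes, for both geometries;
* delimited-text readers/writers and a command-line interface
  (`inst/cli/mixds.R` with `fit`, `select` and `simulate` subcommands).

## Worked example

Simulate a spiked line-transect survey (a common hard case: 70% of the
population is only detectable very close to the line), then fit and compare
mixtures and a K+A model:

```r
library(mixds)
set.seed(1)
spike <- generator("hn-mix", phi = c(0.7, 0.3), sigma = c(0.08, 0.5))
y <- sample_line_distances(function(d) eval_detfun(spike$spec, spike$pars, d),
                           n = 300, w = 1)
surv <- ds_data(y, transect = "line", w = 1, effort = 10, area = 50)
fits <- fit_candidates(surv, mixtures = 1:2, ka = "hn+cos",
                       max_adjustments = 2, seed = 2, quiet = TRUE)
ms <- select_aic(fits)
ms
#> detection function model comparison (AIC-best first):
#>             label  family npar  loglik      aic delta_aic monotone
#> 1 hn 2-pt mixture mixture    3 93.6135 -181.227    0.0000     TRUE
#> 2       hn+cos(2)     K+A    3 87.5566 -169.113   12.1137     TRUE
#> 3 hn 1-pt mixture mixture    1 71.8177 -141.635   39.5915     TRUE
summary(ms$best)
#> 2-point half-normal mixture detection function
#> 3 free parameters
#> n = 300, log-likelihood 93.6135, AIC -181.23
#>    parameter estimate      se
#> 1 log_sigma1 -2.29155 0.13238
#> 2 log_sigma2 -0.58236 0.11586
#> 3 logit_phi1  0.90564 0.26046
#> average detection probability P_a = 0.2770
abundance(ms$best)
#> N_hat = 2707.67 (cv 9.5%), P_a_hat = 0.2770 (cv 9.5%)
#> n = 300 detections; covered area a = 20, study area A = 50
gof_ks(ms$best)   # KS D = 0.046, p = 0.54
```

The 2-point mixture wins by 12 AIC points over the adjusted half-normal
and by almost 40 over the plain half-normal. The fitted component scales
`exp(-2.29) = 0.10` and `exp(-0.58) = 0.56` with weights
`plogis(0.906) = (0.71, 0.29)` recover the spiked generator; the average
detection probability 0.277 (true value 0.250 for this generator) converts
the 300 detections in a covered area of 20 into about 2708 animals in the
study area of 50. The KS p-value of 0.54 shows no evidence of misfit.

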