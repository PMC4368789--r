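---
title: "Mixture detection functions: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture detection functions: models, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixds)
```

## The model

In a distance sampling survey an observer traverses randomly placed lines
or visits randomly placed points and records the distance $y \le w$ to
each detected animal, possibly with covariates $z$ (observer, habitat,
group size, sea state, ...). Detection is certain at distance zero and
declines with distance according to the detection function $g(y, z)$.
`mixds` models $g$ as a finite mixture of $J$ half-normal components,

$$g(y, z) = \sum_{j=1}^{J} \phi_j \exp\!\left(-\frac{y^2}{2\sigma_j(z)^2}\right),
\qquad \phi_j > 0,\ \sum_j \phi_j = 1,$$

with a log-linear covariate model on the scales,
$\sigma_{ij} = \exp(\beta_{0j} + \sum_k \beta_k z_{ik})$: the intercepts
$\beta_{0j}$ differ between components, the slopes $\beta_k$ are shared.
Each component is non-increasing with $g_j(0) = 1$, so the mixture is
automatically monotone non-increasing, bounded in $(0, 1]$ and equal to 1
at zero distance for *any* parameter value. That is the family's central
appeal: the conventional key-plus-adjustment (K+A) models
$g = k(1 + s)/\{k(0)(1 + s(0))\}$ need explicit monotonicity constraints,
those constraints are only enforceable on a finite grid, and they cannot
be applied at all once continuous covariates enter the model. `mixds`
implements the K+A family too — half-normal, hazard-rate
($1 - \exp\{-(y/\sigma)^{-b}\}$, $b > 1$) and uniform keys with cosine,
simple-polynomial or Hermite adjustments — precisely so that both can be
placed in one AIC candidate set.

### Likelihoods

Available objects are uniform in distance for line transects
($\pi(y) = 1/w$) and triangular for points ($\pi(y) = 2y/w^2$).
Conditioning on detection gives the observed-distance densities

$$f_{\text{line}}(y \mid z) = \frac{g(y, z)}{\mu(z)}, \qquad
  f_{\text{point}}(y \mid z) = \frac{2\pi y\, g(y, z)}{\nu(z)},$$

where $\mu(z) = \sum_j \phi_j \int_{l}^{w} g_j$ is the effective strip
width and $\nu(z) = 2\pi \sum_j \phi_j \int_{l}^{w} y\, g_j$ the
effective area of detection, $l$ being an optional left-truncation
distance. For half-normal components both integrals have error-function /
exponential closed forms, which the package uses together with analytic
gradients of both log-likelihoods. Binned distances use the multinomial
likelihood over the interval probabilities (intervals half-open on the
right, the last closed at $w$ — a convention that must simply be fixed).

### Abundance

With $\hat p_i = \mu_i/(w - l)$ (lines) or
$\hat p_i = \nu_i / \{\pi(w^2 - l^2)\}$ (points), abundance follows the
Horvitz–Thompson-like estimator
$\hat N = (A/a) \sum_i 1/\hat p_i$ with covered area $a = 2wL$ or
$\pi w^2 k$, and the average detectability is
$\hat P_a = n/\hat N$ computed at $A = a$, so $\hat N \hat P_a = n$
holds identically.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `J` | 1 | number of mixture components; 1–3 is the practically useful range — each extra component costs 2 parameters and AIC rarely supports more |
| `w`, `left` | — / 0 | truncation distances, in the data's own units (the package never rescales distances; unit invariance is a tested property instead) |
| `restarts` | 5 | optimisation starts; mixture likelihoods are multimodal |
| `control$reltol` | 1e-8 | relative log-likelihood convergence tolerance |
| `control$grtol` | 1e-5 | gradient-norm threshold reported with the convergence flag |
| `control$M` | 20 | constraint/diagnostic grid size for K+A monotonicity (the conventional default of the comparison software) |
| `max_adjustments` | 3 | cap for forward selection over K+A adjustment terms |

## Numerical choices

* **Mixture weights.** The $J-1$ unconstrained weight parameters map to
  the open simplex by a softmax with the last component fixed at zero
  (`mixture_weights()`), reducing to the logistic map at $J = 2$. The map
  is smooth and surjective, the all-zero point is the symmetric mixture,
  and the likelihood can be maximised without constraints. Fitted
  components are reported sorted by ascending scale at the covariate
  reference point, which removes label switching from summaries and
  tests.
* **Starting values.** One start spreads the scale intercepts around a
  half-normal moment estimate, one places them at distance quantiles, and
  the remaining restarts jitter these; weight parameters start at the
  symmetric point. The best finite optimum across starts is kept.
* **Integrals.** Half-normal mixtures (and the unadjusted half-normal
  key, which is the same function) use closed forms; adjusted keys,
  hazard-rate curves and the exponential power series generator integrate
  by a 400-panel composite Simpson rule, vectorised over the grid. For
  the smooth integrands involved the Simpson error is far below the
  optimiser tolerance (about $h^4 f^{(4)}/180 \approx 10^{-9}$ even for a
  scale of $0.02$ at $w = 1$); the test-suite checks the closed forms
  against adaptive quadrature at `1e-8`.
* **Robust closed forms.** $\mu$ suffers catastrophic cancellation when
  $\sigma \gg w$ (the `pnorm` difference underflows); the implementation
  switches to a Taylor expansion of the integral for $w/\sigma < 10^{-3}$,
  and $\nu$ is written with `expm1`. Without this, a mixture component
  drifting to a huge scale during optimisation produces a spurious
  likelihood spike.
* **K+A constraints.** Monotonicity ($g(y_{i+1}) \le g(y_i)$) and
  nonnegativity at $M = 20$ equally spaced distances are imposed through
  an augmented-Lagrangian outer loop around BFGS; the unconstrained
  optimum is tried first and accepted if feasible. With covariates the
  K+A fit is unconstrained (matching standard practice, since the
  constraint set would depend on the covariate values) and the post-fit
  monotonicity flag reports violations — reproducing the failure mode
  that motivates mixtures is deliberate.
* **Degenerate fits.** A fitted proportion below $10^{-4}$, or two scales
  within $10^{-4}$ relative, flags the fit as effectively lower-order;
  invalid parameter decodes return a large finite penalty so optimisers
  can back out.
* **Variance.** The parameter component propagates the inverse observed
  information through numerical sensitivities of $\hat N$ and
  $\hat P_a$; when per-transect counts exist, an encounter-rate component
  from the conventional weighted between-transect variance of the counts
  is added to $\text{var}(\hat N)$. $\hat P_a$ carries the parameter
  component only. The composition is validated against a parametric
  bootstrap in the test-suite (ratio within 25%).
* **Goodness of fit.** The probability-integral transform
  $u_i = F(y_i \mid z_i)$ under the fitted conditional density feeds a
  Kolmogorov–Smirnov test and Q–Q points. The asymptotic p-value ignores
  parameter estimation and is therefore conservative (the observed
  rejection rate under a correctly specified model runs below the nominal
  level); binned data are refused rather than silently approximated.
* **AIC ties** break toward fewer parameters, then mixtures before K+A.

## The simulation harness

`make_scenarios()` ships five scenario groups on $w = 1$: 2-point
line-transect mixtures spanning majority-hard, majority-easy, large-scale
and spiked shapes (group A); the same detection functions with point
geometry (B); 3-point mixtures (C); covariate models with a deterministic
50/50 binary split or fixed standard-normal continuous values (D); and
non-half-normal truth — an exponential power series
$\exp\{-(y/\sigma)^\gamma\}$ and a 2-point hazard-rate mixture (E). The
exact generating parameters behind the original study design were not
published; the shipped tables are qualitative approximations of the
published shapes and every value can be overridden through the `params`
argument. Each scenario exposes its true $P_a$ by quadrature, and all
bias summaries are computed against that oracle, never against an
estimate.

`run_study()` draws each replicate by rejection sampling (uniform
proposals for lines, $w\sqrt{u}$ proposals for points), fits the
candidate set, and records the AIC-best model and $\hat P_a$ within
mixtures-only, K+A-only and combined families. Replicate seeds derive
from the master seed by a counter scheme, so results are byte-identical
across runs; replicates where every fit fails are recorded as missing.

What the generator emulates — and what it does not: datasets are i.i.d.
draws from a known detection function conditional on fixed $n$, with
perfectly measured distances, no responsive movement, no rounding or
heaping, and no spatial structure in animal density. Passing tests
therefore demonstrate the estimator's statistical behaviour under the
model's own assumptions, not robustness to the field artefacts (measurement
error, movement, spiking caused by observer behaviour) that real surveys
add on top.

## Problem sizes used in the checks

The automated checks run replicate studies at 50 replicates per
condition (sample sizes 30–960), 10,000 random parameter draws for the
monotonicity guarantee, 1,000 draws for the integral comparison, a
500-resample bootstrap for the variance calibration and 200 replicates
for the KS size check — sizes chosen to keep Monte-Carlo error well below
the effect sizes being asserted while remaining desk-scale.

## Known limitations

* Only half-normal components are fittable; hazard-rate mixtures and the
  exponential power series exist as data generators to stress-test
  misspecification. Continuous mixtures, component-specific covariate
  slopes and uniform+half-normal hybrids are out of scope.
* Point-transect spikes are intrinsically hard: very few detections come
  from the low-detectability component, and estimates can stay biased at
  any realistic sample size; the harness reproduces this rather than
  fixing it.
* The chi-square goodness of fit for binned data is not implemented (the
  KS path refuses binned data with a pointer); density/stratified designs
  beyond the single encounter-rate component and model averaging are out
  of scope.
* K+A standard errors inherit the usual caveat that constrained maxima
  invalidate the information-matrix estimator; the monotone flag should
  be consulted before trusting them.
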