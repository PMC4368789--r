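Package: mixds
Title: Finite Mixture Detection Functions for Distance Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits detection functions for line- and point-transect distance
    sampling surveys as finite mixtures of half-normal components with
    covariate-dependent scale parameters. Mixture detection functions are
    monotonic non-increasing and bounded in (0, 1] by construction, so no
    constrained optimisation is needed to honour distance sampling
    assumptions. Also provides the conventional key-plus-adjustment family
    (half-normal, hazard-rate or uniform keys with cosine, simple-polynomial
    or Hermite adjustments, fitted with grid monotonicity constraints) as a
    baseline, Horvitz-Thompson abundance estimation with delta-method and
    encounter-rate variance components, AIC model selection with forward
    selection over adjustment terms, Kolmogorov-Smirnov and Q-Q goodness of
    fit, and a simulation harness for replicate studies of estimator
    performance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
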