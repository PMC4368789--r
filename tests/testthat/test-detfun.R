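test_that("component scales follow the log-linear covariate decomposition", {
  expect_equal(component_scale(mix_hn(1), 0, j = 1), 1)
  # zero covariate leaves the intercept scale untouched
  expect_equal(component_scale(mix_hn(1, "x"), c(log(2), 3.7), z = 0, j = 1), 2)
  expect_equal(component_scale(mix_hn(1, "x"), c(0, 1), z = 0.5, j = 1),
               exp(0.5))
  # slopes are shared: j only enters through the intercept
  sp <- mix_hn(2, "x")
  p <- c(log(0.3), log(0.9), 0.8, 0)
  expect_equal(component_scale(sp, p, z = 0.25, j = 2) /
                 component_scale(sp, p, z = 0.25, j = 1), 0.9 / 0.3)
  expect_error(component_scale(mix_hn(1, "x"), c(0, 1), z = c(1, 2), j = 1),
               "covariate")
})

test_that("weight map lands on the open simplex with the right symmetries", {
  expect_identical(mixture_weights(numeric(0)), 1)
  expect_equal(mixture_weights(0), c(0.5, 0.5))
  expect_equal(mixture_weights(c(0, 0)), rep(1 / 3, 3))
  set.seed(42)
  for (i in 1:50) {
    eta <- rnorm(sample(1:4, 1), sd = 4)
    phi <- mixture_weights(eta)
    expect_true(all(phi > 0))
    expect_equal(sum(phi), 1)
  }
  expect_error(mixture_weights(c(0, NaN)), "finite")
})

test_that("mixture evaluation matches the half-normal closed forms", {
  sp1 <- mix_hn(1)
  expect_equal(eval_detfun(sp1, 0, 0), 1)
  expect_equal(eval_detfun(sp1, 0, 1), exp(-0.5))
  # two components, hand-evaluated sum
  sp2 <- mix_hn(2)
  p2 <- c(log(0.5), log(2), 0)
  expect_equal(eval_detfun(sp2, p2, 1),
               0.5 * exp(-2) + 0.5 * exp(-0.125), tolerance = 1e-12)
  expect_error(eval_detfun(sp1, 0, -0.1), "nonnegative")
})

test_that("mixtures are 1 at zero, bounded, non-increasing, phi-linear", {
  set.seed(7)
  ys <- seq(0, 1, length.out = 400)
  for (i in 1:40) {
    J <- sample(1:3, 1)
    K <- sample(0:2, 1)
    sp <- mix_hn(J, covariates = if (K) paste0("z", seq_len(K)))
    p <- random_mix_pars(J, K)
    z <- if (K) rnorm(K) else NULL
    g <- eval_detfun(sp, p, ys, z = z)
    expect_equal(g[1], 1, tolerance = 1e-12)
    expect_true(all(g > 0 & g <= 1 + 1e-12))
    expect_true(all(diff(g) <= 1e-12))
    # component linearity
    d <- mixds:::decode_pars(sp, p)
    comps <- sapply(seq_len(J), function(j)
      eval_detfun(mix_hn(1, covariates = sp$covariates),
                  c(d$beta0[j], d$beta), ys, z = z))
    expect_equal(g, as.vector(comps %*% d$phi), tolerance = 1e-12)
  }
})

test_that("equal-intercept two-point mixture collapses to one point", {
  ys <- seq(0, 1, length.out = 101)
  g2 <- eval_detfun(mix_hn(2), c(log(0.4), log(0.4), 0.7), ys)
  g1 <- eval_detfun(mix_hn(1), log(0.4), ys)
  expect_equal(g2, g1, tolerance = 1e-12)
})

test_that("key functions reproduce their closed forms and standardisation", {
  ys <- seq(0, 1, length.out = 101)
  # half-normal key, no adjustments == one-point mixture
  expect_equal(eval_detfun(ka_spec("hn"), log(0.7), ys),
               eval_detfun(mix_hn(1), log(0.7), ys), tolerance = 1e-12)
  # hazard-rate closed form at sigma = 0.5, b = 2
  expect_equal(eval_detfun(ka_spec("hr"), c(log(0.5), log(1)), 0.5),
               1 - exp(-1), tolerance = 1e-12)
  # zero cosine coefficient on a uniform key is the constant 1
  expect_equal(eval_detfun(ka_spec("unif", "cos", 1), 0, ys, w = 1),
               rep(1, length(ys)))
  # standardisation holds with nonzero adjustments too
  g <- eval_detfun(ka_spec("hn", "cos", 2), c(log(0.4), 0.3, -0.2), ys, w = 1)
  expect_equal(g[1], 1, tolerance = 1e-12)
})

test_that("hazard-rate mixtures evaluate as weighted hazard-rate curves", {
  sp <- mix_hr(2)
  # phi = (0.5, 0.5), sigma = (0.2, 0.6), b = (2, 3)
  p <- c(log(0.2), log(0.6), 0, log(2 - 1), log(3 - 1))
  y <- 0.4
  expect_equal(eval_detfun(sp, p, y),
               0.5 * (1 - exp(-(y / 0.2)^-2)) + 0.5 * (1 - exp(-(y / 0.6)^-3)),
               tolerance = 1e-12)
  expect_equal(eval_detfun(sp, p, 0), 1)
})

test_that("monotonicity check flags adjustment bumps but never mixtures", {
  set.seed(11)
  for (i in 1:25) {
    J <- sample(1:3, 1)
    cm <- check_monotone(mix_hn(J), random_mix_pars(J), w = 1, M = 50)
    expect_true(cm$monotone)
  }
  # large positive second-order cosine forces a secondary bump
  bump <- check_monotone(ka_spec("hn", "cos", 1), c(log(0.3), 1.5),
                         w = 1, M = 20)
  expect_false(bump$monotone)
  expect_gte(length(bump$violations), 1)
  # constant function passes
  flat <- check_monotone(ka_spec("unif", "cos", 1), 0, w = 1, M = 20)
  expect_true(flat$monotone)
})

test_that("degenerate standardisation is refused", {
  # cosine coefficient -1 makes 1 + s(0) = 0 for the uniform key
  expect_error(eval_detfun(ka_spec("unif", "cos", 1), -1, 0.5, w = 1),
               "degenerate standardization")
})
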