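test_that("single-observation line likelihood reduces to log mu", {
  d <- ds_data(0, transect = "line", w = 1)
  mu <- mu_quad(function(y) exp(-y^2 / 2), 1)
  expect_equal(ds_negloglik(0, d, mix_hn(1)), log(mu), tolerance = 1e-10)
  # duplicated observation doubles its contribution
  d2 <- ds_data(c(0.3, 0.3), transect = "line", w = 1)
  d1 <- ds_data(0.3, transect = "line", w = 1)
  expect_equal(ds_negloglik(0.2, d2, mix_hn(1)),
               2 * ds_negloglik(0.2, d1, mix_hn(1)), tolerance = 1e-12)
})

test_that("J = 1 likelihoods equal independent closed-form implementations", {
  set.seed(31)
  dl <- make_line_data(50, 1, 0.5)
  for (ls in c(log(0.3), log(0.5), 0.2)) {
    expect_equal(ds_negloglik(ls, dl, mix_hn(1)),
                 hn_line_nll_oracle(ls, dl$distances, 1), tolerance = 1e-10)
  }
  dp <- make_point_data(50, 1, 0.5)
  for (ls in c(log(0.4), 0)) {
    expect_equal(ds_negloglik(ls, dp, mix_hn(1)),
                 hn_point_nll_oracle(ls, dp$distances, 1), tolerance = 1e-10)
  }
})

test_that("point-transect pdf is normalised and hits the triangular limit", {
  set.seed(5)
  for (i in 1:10) {
    J <- sample(1:2, 1)
    pars <- random_mix_pars(J)
    sp <- mix_hn(J)
    nu <- effective_area(sp, pars, w = 1)
    f <- function(y) 2 * pi * y * eval_detfun(sp, pars, y) / nu
    expect_equal(integrate(f, 0, 1, rel.tol = 1e-10)$value, 1,
                 tolerance = 1e-8)
  }
  # flat-detection limit: f(y) = 2y/w^2
  d <- ds_data(0.5, transect = "point", w = 1)
  expect_equal(exp(-ds_negloglik(log(1e8), d, mix_hn(1))), 1,
               tolerance = 1e-6)
  expect_error(ds_data(c(0, 0.5), transect = "point", w = 1), "degenerate")
})

test_that("binned multinomial likelihood behaves on edge cases and refines", {
  set.seed(8)
  y <- sample_line_distances(function(y) exp(-y^2 / 0.5), 150, 1)
  # single interval: pi_1 = 1 for any parameters
  d1 <- ds_data(y, transect = "line", w = 1, cutpoints = c(0, 1))
  expect_equal(ds_negloglik(log(0.4), d1, mix_hn(1)), 0)
  expect_equal(ds_negloglik(log(2.2), d1, mix_hn(1)), 0)
  # two equal intervals in the flat limit: pi = (1/2, 1/2)
  d2 <- ds_data(y, transect = "line", w = 1, cutpoints = c(0, 0.5, 1))
  expect_equal(ds_negloglik(log(1e7), d2, mix_hn(1)),
               -length(y) * log(0.5), tolerance = 1e-6)
  # fine binning approaches the exact-distance likelihood up to the
  # constant n*log(width) Jacobian of discretisation
  cp64 <- seq(0, 1, length.out = 65)
  d64 <- ds_data(y, transect = "line", w = 1, cutpoints = cp64)
  exact <- ds_negloglik(log(0.5), ds_data(y, transect = "line", w = 1),
                        mix_hn(1))
  binned <- ds_negloglik(log(0.5), d64, mix_hn(1))
  expect_equal(binned + length(y) * log(1 / 64), exact,
               tolerance = 0.01 * length(y))
})

test_that("analytic gradients match central finite differences", {
  set.seed(17)
  dl <- make_line_data(80, c(0.4, 0.6), c(0.15, 0.6))
  dp <- make_point_data(80, c(0.4, 0.6), c(0.2, 0.6))
  for (i in 1:20) {
    J <- sample(1:3, 1)
    pars <- random_mix_pars(J)
    for (dat in list(dl, dp)) {
      ga <- mixds:::nll_grad_mix(pars, dat, mix_hn(J))
      gn <- mixds:::num_grad(function(p) ds_negloglik(p, dat, mix_hn(J)),
                             pars)
      expect_equal(ga, gn, tolerance = 1e-5)
    }
  }
  # covariate slopes included
  set.seed(18)
  zf <- rnorm(60)
  yv <- vapply(zf, function(z)
    sample_line_distances(function(y) exp(-y^2 / (2 * (0.4 * exp(0.3 * z))^2)),
                          1, 1), numeric(1))
  dc <- ds_data(yv, covariates = data.frame(x = zf), transect = "line", w = 1)
  sp <- mix_hn(2, "x")
  for (i in 1:5) {
    pars <- random_mix_pars(2, 1)
    ga <- mixds:::nll_grad_mix(pars, dc, sp)
    gn <- mixds:::num_grad(function(p) ds_negloglik(p, dc, sp), pars)
    expect_equal(ga, gn, tolerance = 1e-5)
  }
})

test_that("left truncation enters both likelihoods through the integrals", {
  set.seed(21)
  y <- runif(40, 0.2, 1)
  dl <- ds_data(y, transect = "line", w = 1, left = 0.2)
  expect_equal(ds_negloglik(log(0.6), dl, mix_hn(1)),
               hn_line_nll_oracle(log(0.6), y, 1, left = 0.2),
               tolerance = 1e-10)
  dp <- ds_data(y, transect = "point", w = 1, left = 0.2)
  expect_equal(ds_negloglik(log(0.6), dp, mix_hn(1)),
               hn_point_nll_oracle(log(0.6), y, 1, left = 0.2),
               tolerance = 1e-10)
})

test_that("distance-unit rescaling shifts the line log-likelihood by n log c", {
  set.seed(23)
  dat <- make_line_data(60, c(0.5, 0.5), c(0.2, 0.7))
  pars <- c(log(0.25), log(0.65), 0.3)
  cc <- 3.7
  dat2 <- ds_data(dat$distances * cc, transect = "line", w = cc, effort = 1)
  pars2 <- c(pars[1:2] + log(cc), pars[3])
  n <- length(dat$distances)
  expect_equal(ds_negloglik(pars2, dat2, mix_hn(2)),
               ds_negloglik(pars, dat, mix_hn(2)) + n * log(cc),
               tolerance = 1e-8)
  # P_a is unit-free
  f1 <- fit_ds(dat, mix_hn(2), seed = 1, restarts = 2)
  f2 <- fit_ds(dat2, mix_hn(2), seed = 1, restarts = 2)
  p1 <- ht_estimate(mixds:::p_per_obs(f1))$P_a_hat
  p2 <- ht_estimate(mixds:::p_per_obs(f2))$P_a_hat
  expect_equal(p1, p2, tolerance = 1e-4)
})

test_that("invalid parameter decodes yield the finite penalty", {
  d <- ds_data(0.5, transect = "line", w = 1)
  expect_equal(ds_negloglik(c(NaN), d, mix_hn(1)), mixds:::PENALTY)
  expect_equal(ds_negloglik(c(Inf), d, mix_hn(1)), mixds:::PENALTY)
  expect_true(is.finite(ds_negloglik(800, d, mix_hn(1))))
})
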