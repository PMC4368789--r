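test_that("one-point fits recover the generating scale", {
  dat <- make_line_data(2000, 1, 0.5, seed = 101)
  f <- fit_ds(dat, mix_hn(1), seed = 1)
  expect_true(f$converged)
  # 3 Monte-Carlo standard errors around sigma = 0.5 (se from the fit)
  se <- sqrt(diag(f$vcov))[1] * exp(f$par[1])
  expect_lt(abs(exp(f$par[1]) - 0.5), 3 * max(se, 0.005))
})

test_that("richer families never fit worse than nested ones", {
  dat <- make_line_data(150, 1, 0.45, seed = 102)
  f1 <- fit_ds(dat, mix_hn(1), seed = 2)
  f2 <- fit_ds(dat, mix_hn(2), seed = 2)
  expect_gte(f2$loglik, f1$loglik - 1e-6)
  expect_equal(f1$aic, 2 * f1$npar - 2 * f1$loglik)
  expect_equal(f2$aic, 2 * f2$npar - 2 * f2$loglik)
})

test_that("half-normal key with no adjustments is the one-point mixture", {
  dat <- make_line_data(120, c(0.4, 0.6), c(0.2, 0.6), seed = 103)
  fm <- fit_ds(dat, mix_hn(1), seed = 3)
  fk <- fit_ds(dat, ka_spec("hn"), seed = 3)
  expect_equal(fk$loglik, fm$loglik, tolerance = 1e-10)
  ys <- seq(0, 1, length.out = 50)
  expect_equal(eval_detfun(fk$spec, fk$par, ys, w = 1),
               eval_detfun(fm$spec, fm$par, ys), tolerance = 1e-6)
})

test_that("constrained key+adjustment fits come out monotone on easy data", {
  dat <- make_line_data(150, 1, 0.5, seed = 104)
  f <- fit_ds(dat, ka_spec("hn", "cos", 2), seed = 4, restarts = 2)
  expect_true(f$monotone)
  expect_true(f$converged)
})

test_that("fits are reproducible from the seed and canonically ordered", {
  dat <- make_line_data(200, c(0.4, 0.6), c(0.12, 0.6), seed = 105)
  fa <- fit_ds(dat, mix_hn(2), seed = 9)
  fb <- fit_ds(dat, mix_hn(2), seed = 9)
  expect_identical(fa$par, fb$par)
  # ascending scale ordering at the reference point
  expect_lt(fa$par[1], fa$par[2])
})

test_that("covariance is symmetric positive semidefinite at the optimum", {
  dat <- make_line_data(300, c(0.4, 0.6), c(0.15, 0.6), seed = 106)
  f <- fit_ds(dat, mix_hn(2), seed = 5)
  V <- vcov(f)
  expect_equal(V, t(V), tolerance = 1e-8)
  expect_true(all(eigen(V, symmetric = TRUE)$values > -1e-8))
  expect_lt(f$grad_norm, 1e-2 * (1 + abs(f$loglik)))
})

test_that("covariate models fit and report expanded parameter names", {
  set.seed(107)
  zf <- factor(rep(c("a", "b"), each = 50))
  zi <- as.numeric(zf == "b")
  y <- vapply(zi, function(z)
    sample_line_distances(function(y)
      exp(-y^2 / (2 * (0.3 * exp(0.8 * z))^2)), 1, 1), numeric(1))
  dat <- ds_data(y, covariates = data.frame(g = zf), transect = "line", w = 1)
  f <- fit_ds(dat, mix_hn(1, covariates = "gb"), seed = 6)
  expect_true(f$converged)
  expect_named(coef(f), c("log_sigma1", "gb"))
  # slope should be materially positive for this separation
  expect_gt(coef(f)["gb"], 0.2)
})

test_that("small samples warn and degenerate mixtures are flagged", {
  dat <- make_line_data(2, 1, 0.5, seed = 108)
  expect_warning(try(fit_ds(dat, mix_hn(2), seed = 7, restarts = 1),
                     silent = TRUE),
                 "fewer observations")
  # data from one component: a 2-point fit usually collapses
  dat2 <- make_line_data(300, 1, 0.5, seed = 109)
  f <- fit_ds(dat2, mix_hn(2), seed = 7)
  d <- mixds:::decode_pars(f$spec, f$par)
  collapsed <- any(d$phi < 1e-4) ||
    abs(diff(exp(f$par[1:2]))) / exp(f$par[1]) < 1e-4
  expect_equal(f$degenerate, collapsed)
})

test_that("methods surface the fit: print, summary, predict, residuals, plot", {
  dat <- make_line_data(100, 1, 0.5, seed = 110, effort = 1)
  f <- fit_ds(dat, mix_hn(1), seed = 8)
  expect_output(print(f), "mixture detection function")
  s <- summary(f)
  expect_s3_class(s$coefficients, "data.frame")
  expect_named(s$coefficients, c("parameter", "estimate", "se"))
  expect_equal(AIC(f), f$aic)
  p <- predict(f)
  expect_true(all(p > 0 & p <= 1))
  g <- predict(f, type = "detection", distance = c(0, 0.5))
  expect_equal(g[1], 1)
  u <- residuals(f)
  expect_true(all(u >= 0 & u <= 1))
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp); plot(f); grDevices::dev.off()
  expect_true(file.exists(tmp))
  unlink(tmp)
  sims <- simulate(f, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "ds_data")
})
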