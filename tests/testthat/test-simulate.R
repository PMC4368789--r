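test_that("line sampler reproduces the target distribution", {
  set.seed(401)
  # accept-all: uniform on (0, w)
  y <- sample_line_distances(function(y) rep(1, length(y)), 5000, 1)
  expect_gt(suppressWarnings(ks.test(y, "punif"))$p.value, 0.01)
  # truncated half-normal mean vs quadrature oracle
  set.seed(402)
  y <- sample_line_distances(function(y) exp(-y^2 / (2 * 0.25)), 10000, 1)
  mu <- mu_quad(function(y) exp(-y^2 / 0.5), 1)
  m_true <- integrate(function(y) y * exp(-y^2 / 0.5) / mu, 0, 1)$value
  v_true <- integrate(function(y) (y - m_true)^2 * exp(-y^2 / 0.5) / mu,
                      0, 1)$value
  expect_lt(abs(mean(y) - m_true), 3 * sqrt(v_true / 10000))
  # determinism
  set.seed(7); a <- sample_line_distances(function(y) exp(-y^2), 50, 1)
  set.seed(7); b <- sample_line_distances(function(y) exp(-y^2), 50, 1)
  expect_identical(a, b)
})

test_that("point sampler reproduces the triangular-weighted distribution", {
  set.seed(403)
  y <- sample_point_distances(function(y) rep(1, length(y)), 10000, 1)
  expect_lt(abs(mean(y) - 2 / 3), 3 * sqrt(1 / 18 / 10000))
  # accept-all quantiles follow the w*sqrt(u) transform
  qs <- quantile(y, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(qs, sqrt(c(0.25, 0.5, 0.75)), tolerance = 0.02)
  # half-normal g: empirical mean vs the 2*pi*y*g/nu density oracle
  set.seed(404)
  y <- sample_point_distances(function(y) exp(-y^2 / 2), 10000, 1)
  nu <- nu_quad(function(y) exp(-y^2 / 2), 1)
  m_true <- integrate(function(y) y * 2 * pi * y * exp(-y^2 / 2) / nu,
                      0, 1)$value
  expect_lt(abs(mean(y) - m_true), 3 * sd(y) / sqrt(10000))
})

test_that("histograms of sampled distances match the target pdf (chi-square)", {
  set.seed(405)
  gen <- generator("hn-mix", phi = c(0.6, 0.4), sigma = c(0.15, 0.7))
  gf <- function(y) eval_detfun(gen$spec, gen$pars, y)
  y <- sample_line_distances(gf, 50000, 1)
  br <- seq(0, 1, length.out = 51)
  obs <- table(cut(y, br))
  mu <- mu_quad(gf, 1)
  pr <- vapply(seq_len(50), function(i)
    integrate(gf, br[i], br[i + 1])$value / mu, numeric(1))
  expect_gt(suppressWarnings(chisq.test(obs, p = pr / sum(pr)))$p.value, 0.01)
})

test_that("scenario groups carry the documented structure", {
  A <- make_scenarios("A", n = 60)
  expect_length(A, 4)
  expect_true(all(vapply(A, function(s) s$transect, "") == "line"))
  B <- make_scenarios("B", n = 60)
  expect_length(B, 4)
  expect_true(all(vapply(B, function(s) s$transect, "") == "point"))
  # group B reuses the group-A detection functions
  expect_equal(B[[2]]$generator$pars, A[[2]]$generator$pars)
  expect_equal(unname(vapply(B, function(s) s$label, "")),
               c("B1", "B2", "B3", "B4"))
  D <- make_scenarios("D", n = 40)
  expect_equal(D$D1$covariate_gen, "binary")
  expect_equal(D$D2$covariate_gen, "normal")
  E <- make_scenarios("E")
  expect_equal(E$E1$generator$family, "eps")
  expect_equal(E$E2$generator$family, "hr-mix")
  # every generator is a valid detection function: g(0) = 1, monotone
  for (gr in list(A, make_scenarios("C"), E)) {
    for (sc in gr) {
      cm <- check_monotone(sc$generator$spec, sc$generator$pars, w = 1,
                           M = 200)
      expect_true(cm$monotone)
      expect_equal(eval_detfun(sc$generator$spec, sc$generator$pars, 0), 1)
    }
  }
})

test_that("binary covariate scenario splits observations exactly in half", {
  D <- make_scenarios("D", n = 40)
  dat <- simulate_scenario(D$D1, seed = 5)
  expect_equal(as.vector(table(dat$covariates$cov)), c(20, 20))
  expect_equal(colnames(dat$Z), "covb")
})

test_that("true P_a agrees with the closed-form oracle", {
  A <- make_scenarios("A")
  # A1: phi-weighted mu / w
  mu <- 0.7 * mu_quad(function(y) exp(-y^2 / (2 * 0.04)), 1) +
        0.3 * mu_quad(function(y) exp(-y^2 / (2 * 0.64)), 1)
  expect_equal(true_pa(A$A1), mu, tolerance = 1e-8)
  B <- make_scenarios("B")
  nu <- 0.7 * nu_quad(function(y) exp(-y^2 / (2 * 0.04)), 1) +
        0.3 * nu_quad(function(y) exp(-y^2 / (2 * 0.64)), 1)
  expect_equal(true_pa(B$B1), nu / pi, tolerance = 1e-8)
  # binary covariate: exact average over the two levels
  D <- make_scenarios("D")
  g0 <- function(y) 0.4 * exp(-y^2 / (2 * 0.15^2)) + 0.6 * exp(-y^2 / (2 * 0.6^2))
  g1 <- function(y) 0.4 * exp(-y^2 / (2 * (0.15 * exp(0.7))^2)) +
    0.6 * exp(-y^2 / (2 * (0.6 * exp(0.7))^2))
  expect_equal(true_pa(D$D1), 0.5 * (mu_quad(g0, 1) + mu_quad(g1, 1)),
               tolerance = 1e-8)
})

test_that("replicate studies are reproducible and tabulate selections", {
  sc <- make_scenarios("A", n = 50)$A1
  st1 <- run_study(sc, replicates = 2, seed = 11, mixtures = 1,
                   ka = character(0), restarts = 1)
  st2 <- run_study(sc, replicates = 2, seed = 11, mixtures = 1,
                   ka = character(0), restarts = 1)
  expect_identical(st1$records, st2$records)
  # single candidate family: it is always the selected model
  expect_true(all(st1$records$best_mixture == "hn 1-pt mixture"))
  expect_true(all(!is.na(st1$records$pa_combined)))
  expect_named(st1$summary,
               c("scenario", "n", "true_pa", "median_pa_mixture",
                 "median_pa_ka", "median_pa_combined", "bias_combined",
                 "prop_generating_form", "failed"))
})
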