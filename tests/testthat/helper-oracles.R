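# Independent oracles and small data builders shared across tests.
# These deliberately avoid the package's own integral/likelihood code paths.

# adaptive-quadrature oracles for the normalising integrals
mu_quad <- function(gfun, w, left = 0) {
  stats::integrate(gfun, left, w, rel.tol = 1e-12)$value
}
nu_quad <- function(gfun, w, left = 0) {
  stats::integrate(function(y) 2 * pi * y * gfun(y), left, w,
                   rel.tol = 1e-12)$value
}

# closed-form half-normal line-transect negative log-likelihood, written
# directly from the density g(y)/mu without touching package internals
hn_line_nll_oracle <- function(log_sigma, y, w, left = 0) {
  s <- exp(log_sigma)
  mu <- s * sqrt(2 * pi) * (pnorm(w / s) - pnorm(left / s))
  sum(y^2 / (2 * s^2)) + length(y) * log(mu)
}

# closed-form half-normal point-transect negative log-likelihood
hn_point_nll_oracle <- function(log_sigma, y, w, left = 0) {
  s <- exp(log_sigma)
  nu <- 2 * pi * s^2 * (exp(-left^2 / (2 * s^2)) - exp(-w^2 / (2 * s^2)))
  -sum(log(2 * pi * y) - y^2 / (2 * s^2) - log(nu))
}

# random mixture parameter vector (J components, K covariates)
random_mix_pars <- function(J, K = 0) {
  c(stats::runif(J, log(0.05), log(3)),
    if (K) stats::rnorm(K, sd = 0.5),
    if (J > 1) stats::rnorm(J - 1, sd = 1.5))
}

# vectorised half-normal mixture curve from natural parameters
hn_mix_curve <- function(phi, sigma) {
  function(y) {
    out <- 0
    for (j in seq_along(phi)) out <- out + phi[j] * exp(-y^2 / (2 * sigma[j]^2))
    out
  }
}

# quick line dataset from a half-normal mixture
make_line_data <- function(n, phi, sigma, w = 1, seed = NULL, effort = 1) {
  if (!is.null(seed)) set.seed(seed)
  y <- sample_line_distances(hn_mix_curve(phi, sigma), n, w)
  ds_data(y, transect = "line", w = w, effort = effort)
}

make_point_data <- function(n, phi, sigma, w = 1, seed = NULL, effort = 1) {
  if (!is.null(seed)) set.seed(seed)
  y <- sample_point_distances(hn_mix_curve(phi, sigma), n, w)
  ds_data(y, transect = "point", w = w, effort = effort)
}
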