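# Line-, point-, and binned-likelihoods.
#
# Exact distances, line transect: the pdf of an observed distance given the
# covariates is f(y|z) = g(y,z)/mu(z), so
#     -loglik = -sum_i [ log g(y_i, z_i) - log mu_i ].
# Point transect: f(y|z) = 2*pi*y*g(y,z)/nu(z), so
#     -loglik = -sum_i [ log(2*pi*y_i) + log g(y_i, z_i) - log nu_i ].
# Binned distances: multinomial over the interval probabilities pi_c, the
# ratio of the mu- (line) or nu- (point) integral over the interval to the
# integral over [left, w].
#
# Invalid parameter decodes (overflowing scales, non-finite values) return a
# large finite penalty so unconstrained optimisers can recover.

#' Negative log-likelihood of a detection-function model
#'
#' Dispatches on the survey geometry and on whether the data are binned.
#' Exposed mainly for diagnostics and tests; [fit_ds()] drives it.
#'
#' @param pars parameter vector for \code{spec}.
#' @param data a [ds_data()] object.
#' @param spec a \code{detfun_spec}.
#' @return a single finite value (a large penalty is returned where the
#'   likelihood is not evaluable).
#' @export
ds_negloglik <- function(pars, data, spec) {
  if (!all(is.finite(pars))) return(PENALTY)
  out <- tryCatch({
    if (!is.null(data$cutpoints)) nll_binned(pars, data, spec)
    else if (data$transect == "line") nll_line(pars, data, spec)
    else nll_point(pars, data, spec)
  }, error = function(e) PENALTY)
  if (!is.finite(out)) PENALTY else out
}

nll_line <- function(pars, data, spec) {
  Z <- spec_design(spec, data)
  g <- eval_detfun(spec, pars, data$distances,
                   z = if (ncol(Z)) Z else NULL, w = data$w)
  mu <- int_detfun(spec, pars, Z, data$w, data$left, weighted = FALSE)
  if (any(g <= 0) || any(mu <= 0)) return(PENALTY)
  -(sum(log(g)) - sum(log(mu)))
}

nll_point <- function(pars, data, spec) {
  y <- data$distances
  if (any(y <= 0) && data$left == 0)
    stop("degenerate observation: y = 0 has zero density for point transects")
  Z <- spec_design(spec, data)
  g <- eval_detfun(spec, pars, y, z = if (ncol(Z)) Z else NULL, w = data$w)
  nu <- int_detfun(spec, pars, Z, data$w, data$left, weighted = TRUE)
  if (any(g <= 0) || any(nu <= 0)) return(PENALTY)
  -(sum(log(2 * pi * y)) + sum(log(g)) - sum(log(nu)))
}

nll_binned <- function(pars, data, spec) {
  cp <- data$cutpoints
  nbin <- length(cp) - 1L
  Z <- spec_design(spec, data)
  weighted <- data$transect == "point"
  # interval integrals per unique covariate row
  Zu <- unique(Z)
  if (nrow(Zu) == 0L) Zu <- matrix(0, 1L, 0L)
  rowkey <- if (ncol(Z)) apply(Z, 1L, paste, collapse = "\r") else
    rep("", nrow(Z))
  ukey <- if (ncol(Zu)) apply(Zu, 1L, paste, collapse = "\r") else ""
  ridx <- match(rowkey, ukey)
  P <- matrix(0, nrow(Zu), nbin)
  for (u in seq_len(nrow(Zu))) {
    zu <- if (ncol(Zu)) Zu[u, , drop = FALSE] else NULL
    ints <- vapply(seq_len(nbin), function(c) {
      int_detfun(spec, pars, z_matrix(zu, ncol(Z), 1L), cp[c + 1L], cp[c],
                 weighted = weighted)
    }, numeric(1))
    P[u, ] <- ints / sum(ints)
  }
  if (any(!is.finite(P)) || any(P <= 0)) return(PENALTY)
  -sum(log(P[cbind(ridx, data$bin)]))
}

# --- analytic gradient (half-normal mixtures, exact distances) --------------

# gradient of the negative log-likelihood wrt c(beta0, beta, eta)
nll_grad_mix <- function(pars, data, spec) {
  d <- decode_pars(spec, pars)
  J <- spec$J; K <- length(spec$covariates)
  y <- data$distances; n <- length(y)
  w <- data$w; l <- data$left
  Z <- spec_design(spec, data)
  sig <- scale_mat(d$beta0, d$beta, Z)               # n x J
  phi <- d$phi
  Ym <- matrix(y, n, J)
  E <- hn_kernel(Ym, sig)                            # component g values
  dE <- E * Ym^2 / sig^3                             # dE/dsigma
  Bw <- exp(-w^2 / (2 * sig^2)); Bl <- exp(-l^2 / (2 * sig^2))
  if (data$transect == "line") {
    M <- mu_hn_closed(sig, w, l)
    dM <- M / sig - (w * Bw - l * Bl) / sig
    denom_g <- as.vector(E %*% phi)
    denom_m <- as.vector(M %*% phi)
  } else {
    M <- nu_hn_closed(sig, w, l)
    dM <- 2 * M / sig + 2 * pi * (l^2 * Bl - w^2 * Bw) / sig
    denom_g <- as.vector(E %*% phi)
    denom_m <- as.vector(M %*% phi)
  }
  # per-(i,j) contribution of d sigma_ij to the loglik
  W <- sweep(dE / denom_g - dM / denom_m, 2, phi, "*") * sig
  g_beta0 <- colSums(W)
  g_beta <- if (K) as.vector(t(Z) %*% rowSums(W)) else numeric(0)
  # weight parameters: d loglik / d eta_m via softmax Jacobian
  R <- E / denom_g - M / denom_m                     # n x J
  Rphi <- as.vector(R %*% phi)
  g_eta <- if (J > 1) {
    vapply(seq_len(J - 1), function(m) sum(phi[m] * (R[, m] - Rphi)),
           numeric(1))
  } else numeric(0)
  -c(g_beta0, g_beta, g_eta)
}

# gradient usable by optim: analytic where available, else central FD
nll_gradient <- function(pars, data, spec) {
  analytic <- inherits(spec, "mix_spec") && spec$component == "hn" &&
    is.null(data$cutpoints)
  if (analytic && all(is.finite(pars))) {
    g <- tryCatch(nll_grad_mix(pars, data, spec), error = function(e) NULL)
    if (!is.null(g) && all(is.finite(g))) return(g)
  }
  num_grad(function(p) ds_negloglik(p, data, spec), pars)
}
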