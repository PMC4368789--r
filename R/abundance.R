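#' Per-observation detection probability within the covered area
#'
#' For line transects \eqn{\hat p_i = \mu_i / (w - l)}; for point transects
#' \eqn{\hat p_i = \nu_i / \{\pi(w^2 - l^2)\}}. Values lie in \eqn{(0, 1]}.
#'
#' @param fit a converged \code{ds_fit}.
#' @param Z optional design matrix of covariate rows (defaults to the
#'   fitting data); internal callers pass it directly.
#' @param pars optional parameter vector overriding the MLE (used by the
#'   delta-method sensitivities).
#' @return numeric vector of \eqn{\hat p_i}, one per covariate row (length
#'   1 for models without covariates).
#' @export
detection_prob <- function(fit, Z = NULL, pars = NULL) {
  stopifnot(inherits(fit, "ds_fit"))
  if (is.null(pars) && !fit$converged)
    stop("refusing to compute detection probabilities from a non-converged fit")
  data <- fit$data
  pars <- pars %||% fit$par
  Z <- Z %||% spec_design(fit$spec, data)
  z <- if (ncol(Z)) Z else NULL
  if (data$transect == "line") {
    mu <- int_detfun(fit$spec, pars, Z, data$w, data$left, weighted = FALSE)
    mu / (data$w - data$left)
  } else {
    nu <- int_detfun(fit$spec, pars, Z, data$w, data$left, weighted = TRUE)
    nu / (pi * (data$w^2 - data$left^2))
  }
}

# expand a length-1 p (no covariates) to n observations
p_per_obs <- function(fit, pars = NULL) {
  p <- detection_prob(fit, pars = pars)
  n <- length(fit$data$distances)
  if (length(p) == 1L) rep(p, n) else p
}

#' Horvitz-Thompson abundance and average detectability
#'
#' The Horvitz-Thompson-like estimator
#' \deqn{\hat N = \frac{A}{a} \sum_{i=1}^n \frac{1}{\hat p_i},}
#' where \eqn{a = 2wL} for line transects and \eqn{a = \pi w^2 k} for point
#' transects, together with the average detection probability
#' \eqn{\hat P_a = n / \hat N_{A=a}} (computed with \eqn{A = a} regardless
#' of the study-area scaling, so \eqn{\hat N \hat P_a = n} exactly when
#' \eqn{A = a}).
#'
#' Variances combine (i) a delta-method component propagating the parameter
#' covariance through numerical sensitivities of \eqn{\hat N} and
#' \eqn{\hat P_a}, and (ii), for \eqn{\hat N} when per-transect counts are
#' available, an encounter-rate component from between-transect variation
#' in counts (the conventional weighted between-transect estimator). With a
#' single transect the encounter-rate component is zero and a note is
#' recorded.
#'
#' @param fit a converged \code{ds_fit} whose data carry \code{effort} (and
#'   optionally \code{area}, \code{transect_id}).
#' @return object of class \code{ds_abundance}: list with \code{p_i},
#'   \code{N_hat}, \code{P_a_hat}, \code{var_N}, \code{var_P_a},
#'   \code{cv_N}, \code{cv_P_a} (percent), \code{a}, \code{A}, \code{n}.
#' @export
abundance <- function(fit) {
  stopifnot(inherits(fit, "ds_fit"))
  data <- fit$data
  if (is.null(data$effort))
    stop("abundance estimation needs effort (L or k) in the data")
  a <- covered_area(data)
  A <- data$area %||% a
  p <- p_per_obs(fit)
  n <- length(data$distances)
  ht <- ht_estimate(p, A, a)
  N_hat <- ht$N_hat
  P_a <- ht$P_a_hat

  # delta-method parameter components
  V <- fit$vcov
  var_par_N <- var_par_P <- NA_real_
  if (all(is.finite(V)) && length(fit$par)) {
    gN <- num_grad(function(th) {
      pp <- p_obs_at(fit, th); (A / a) * sum(1 / pp)
    }, fit$par)
    gP <- num_grad(function(th) {
      pp <- p_obs_at(fit, th); n / sum(1 / pp)
    }, fit$par)
    var_par_N <- max(0, as.numeric(t(gN) %*% V %*% gN))
    var_par_P <- max(0, as.numeric(t(gP) %*% V %*% gP))
  } else {
    warning("parameter covariance unavailable; reporting encounter-rate component only")
  }

  # encounter-rate component (between-transect variation in n)
  var_er_N <- 0
  if (!is.null(data$transect_id) &&
      length(unique(data$transect_id)) > 1L) {
    var_n <- encounter_rate_var(data)
    # N_hat = (A/a) * n * (mean of 1/p); scale var(n) by (N_hat/n)^2
    var_er_N <- var_n * (N_hat / n)^2
  }
  var_N <- (if (is.na(var_par_N)) 0 else var_par_N) + var_er_N
  var_P <- var_par_P
  structure(list(p_i = p, N_hat = N_hat, P_a_hat = P_a,
                 var_N = var_N, var_P_a = var_P,
                 var_N_param = var_par_N, var_N_er = var_er_N,
                 cv_N = 100 * sqrt(var_N) / N_hat,
                 cv_P_a = 100 * sqrt(var_P) / P_a,
                 a = a, A = A, n = n),
            class = "ds_abundance")
}

#' Horvitz-Thompson arithmetic from detection probabilities
#'
#' The pure estimator step: \eqn{\hat N = (A/a) \sum_i 1/\hat p_i} and
#' \eqn{\hat P_a = n / \sum_i 1/\hat p_i} (i.e. \eqn{n/\hat N} at
#' \eqn{A = a}). Exposed so the estimator identities can be examined on any
#' probability vector.
#'
#' @param p vector of per-observation detection probabilities in (0, 1].
#' @param A study area.
#' @param a covered area.
#' @return list with \code{N_hat} and \code{P_a_hat}.
#' @export
ht_estimate <- function(p, A = 1, a = 1) {
  if (any(p <= 0)) stop("nonpositive detection probability encountered")
  s <- sum(1 / p)
  list(N_hat = (A / a) * s, P_a_hat = length(p) / s)
}

covered_area <- function(data) {
  if (data$transect == "line") 2 * data$w * data$effort
  else pi * data$w^2 * data$effort
}

# detection probabilities per observation at an arbitrary parameter vector
p_obs_at <- function(fit, pars) {
  p <- detection_prob(fit, pars = pars)
  n <- length(fit$data$distances)
  if (length(p) == 1L) rep(p, n) else p
}

# conventional weighted between-transect variance of the total count:
# var(n) = L * K/(K-1) * sum_k l_k (n_k/l_k - n/L)^2  (lines; points use
# unit effort per point)
encounter_rate_var <- function(data) {
  ids <- data$transect_id
  tab <- table(ids)
  Kt <- length(tab)
  if (Kt < 2L) return(0)
  eff <- data$transect_effort
  if (is.null(eff)) {
    eff <- stats::setNames(rep((data$effort %||% Kt) / Kt, Kt), names(tab))
  }
  eff <- eff[names(tab)]
  L <- sum(eff)
  n <- length(ids)
  er <- as.numeric(tab) / eff
  L * Kt / (Kt - 1) * sum(eff * (er - n / L)^2)
}

#' @export
print.ds_abundance <- function(x, ...) {
  cat(sprintf("N_hat = %.2f (cv %.1f%%), P_a_hat = %.4f (cv %.1f%%)\n",
              x$N_hat, x$cv_N, x$P_a_hat, x$cv_P_a))
  cat(sprintf("n = %d detections; covered area a = %g, study area A = %g\n",
              x$n, x$a, x$A))
  invisible(x)
}
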