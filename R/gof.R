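# Goodness of fit via the probability-integral transform.
#
# For each observation the fitted conditional cdf is
#   line:  F(y|z) = mu(left, y; z) / mu(left, w; z)
#   point: F(y|z) = nu(left, y; z) / nu(left, w; z)
# Under a correct model the transformed sample is Uniform(0, 1), which is
# tested with a Kolmogorov-Smirnov test. With estimated parameters the
# asymptotic p-value is conservative (rejection rate below nominal).

cdf_transform <- function(fit) {
  data <- fit$data
  if (!is.null(data$cutpoints))
    stop("Kolmogorov-Smirnov GOF needs exact distances; ",
         "chi-square GOF for binned data is not provided")
  y <- data$distances
  Z <- spec_design(fit$spec, data)
  weighted <- data$transect == "point"
  spec <- fit$spec; pars <- fit$par
  if (inherits(spec, "mix_spec") && spec$component == "hn") {
    d <- decode_pars(spec, pars)
    sig <- scale_mat(d$beta0, d$beta, Z)
    num <- if (weighted) {
      nu_part <- 2 * pi * sig^2 *
        (exp(-data$left^2 / (2 * sig^2)) - exp(-y^2 / (2 * sig^2)))
      as.vector(nu_part %*% d$phi)
    } else {
      as.vector(mu_hn_closed(sig, y, data$left) %*% d$phi)
    }
    den <- int_detfun(spec, pars, Z, data$w, data$left, weighted = weighted)
    num / den
  } else {
    den <- int_detfun(spec, pars, Z, data$w, data$left, weighted = weighted)
    vapply(seq_along(y), function(i) {
      zi <- if (ncol(Z)) Z[i, , drop = FALSE] else NULL
      num <- int_detfun(spec, pars, z_matrix(zi, ncol(Z), 1L),
                        y[i], data$left, weighted = weighted)
      num / den[i]
    }, numeric(1))
  }
}

#' Kolmogorov-Smirnov goodness-of-fit test
#'
#' Transforms each observed distance by the fitted conditional cdf
#' \eqn{F(y_i | z_i)} and tests the transformed sample for uniformity.
#' Reports the KS statistic \eqn{D} and the asymptotic p-value; because the
#' parameters are estimated from the same data, the test is conservative.
#'
#' @param fit a \code{ds_fit} on exact (unbinned) distances.
#' @return list with elements \code{D} and \code{p_value}.
#' @export
gof_ks <- function(fit) {
  u <- cdf_transform(fit)
  kt <- suppressWarnings(stats::ks.test(u, "punif"))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Quantile-quantile points for a fitted detection function
#'
#' Pairs the fitted cdf values \eqn{F(y_{(i)} | z_{(i)})} (ordered) with the
#' empirical cdf plotting positions \eqn{(i - 0.5)/n}. Points close to the
#' diagonal indicate a good fit.
#'
#' @param fit a \code{ds_fit} on exact distances.
#' @return data.frame with columns \code{fitted} and \code{empirical}.
#' @export
qq_points <- function(fit) {
  u <- sort(cdf_transform(fit))
  n <- length(u)
  data.frame(fitted = u, empirical = (seq_len(n) - 0.5) / n)
}
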