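# Effective strip width and effective detection area.
#
# For half-normal components both integrals have closed forms:
#   int_l^w exp(-y^2/2s^2) dy = s * sqrt(2*pi) * (pnorm(w/s) - pnorm(l/s))
#   2*pi * int_l^w y exp(-y^2/2s^2) dy
#       = 2*pi*s^2 * (exp(-l^2/2s^2) - exp(-w^2/2s^2))
# Everything else (hazard-rate components/keys, adjusted keys) goes through
# adaptive quadrature.

mu_hn_closed <- function(sigma, w, left = 0) {
  a <- w / sigma; b <- left / sigma
  direct <- sigma * sqrt(2 * pi) * (stats::pnorm(a) - stats::pnorm(b))
  # pnorm differences cancel catastrophically when sigma >> w; switch to the
  # Taylor expansion of the integral there (relative error ~ (w/sigma)^6)
  small <- a < 1e-3
  if (any(small)) {
    series <- (w - left) - (w^3 - left^3) / (6 * sigma^2) +
      (w^5 - left^5) / (40 * sigma^4)
    direct[small] <- series[small]
  }
  direct
}

nu_hn_closed <- function(sigma, w, left = 0) {
  # exp(-l^2/2s^2) - exp(-w^2/2s^2) rewritten via expm1 to survive sigma >> w
  2 * pi * sigma^2 * exp(-left^2 / (2 * sigma^2)) *
    (-expm1(-(w^2 - left^2) / (2 * sigma^2)))
}

# composite Simpson rule, vectorised over the integrand evaluations; 400
# panels keep the error far below the optimizer tolerances for the smooth
# detection functions integrated here (see the methods vignette)
simpson_w <- function(npanel) {
  wts <- c(1, rep(c(4, 2), npanel / 2 - 1), 4, 1)
  wts / 3
}
SIMPSON_N <- 400L

# quadrature over unique covariate rows; gfun gets (y, row-index)
quad_rows <- function(gfun, Z, w, left, weighted) {
  key <- if (ncol(Z)) apply(Z, 1L, paste, collapse = "\r") else rep("", nrow(Z))
  uq <- !duplicated(key)
  idx <- match(key, key[uq])
  h <- (w - left) / SIMPSON_N
  ys <- seq(left, w, length.out = SIMPSON_N + 1L)
  wts <- simpson_w(SIMPSON_N) * h
  if (weighted) wts <- wts * 2 * pi * ys
  vals <- vapply(which(uq), function(i) sum(wts * gfun(ys, i)), numeric(1))
  vals[idx]
}

int_detfun <- function(spec, pars, Z, w, left, weighted) {
  if (left >= w) stop("left truncation distance must be below w")
  n <- max(1L, nrow(Z))
  d <- decode_pars(spec, pars)
  if (inherits(spec, "mix_spec") && spec$component == "hn") {
    sig <- scale_mat(d$beta0, d$beta, Z)
    m <- if (weighted) nu_hn_closed(sig, w, left) else mu_hn_closed(sig, w, left)
    return(as.vector(m %*% d$phi))
  }
  # an unadjusted half-normal key is a one-point mixture: use its closed form
  if (inherits(spec, "ka_spec") && spec$key == "hn" && spec$nadj == 0L) {
    lp <- if (length(d$beta)) as.vector(Z %*% d$beta) else rep(0, n)
    sig <- d$sigma0 * exp(lp)
    return(if (weighted) nu_hn_closed(sig, w, left)
           else mu_hn_closed(sig, w, left))
  }
  gfun <- function(y, i) {
    zi <- if (ncol(Z)) Z[i, ] else NULL
    eval_detfun(spec, pars, y, z = zi, w = w)
  }
  quad_rows(gfun, Z, w, left, weighted)
}

#' Effective strip width
#'
#' The line-transect normalising integral
#' \eqn{\mu_i(z_i) = \sum_j \phi_j \int_{l}^{w} g_j(y, z_i)\,dy}: the
#' half-width of a fully censused strip that would yield the same expected
#' count as the survey. Closed-form (error-function based) for half-normal
#' mixtures, adaptive quadrature otherwise. Always in \eqn{(0, w - l]}.
#'
#' @inheritParams eval_detfun
#' @param left left-truncation distance (default 0); must be below \code{w}.
#' @return numeric vector of \eqn{\mu_i}, one per covariate row (length 1
#'   with no covariates).
#' @export
effective_strip_width <- function(spec, pars, z = NULL, w, left = 0) {
  Z <- z_matrix(z, length(spec$covariates),
                if (is.null(z) || is.null(dim(z))) 1L else nrow(as.matrix(z)))
  int_detfun(spec, pars, Z, w, left, weighted = FALSE)
}

#' Effective area of detection
#'
#' The point-transect normalising integral
#' \eqn{\nu_i = 2\pi \sum_j \phi_j \int_{l}^{w} y\, g_j(y, z_i)\,dy}: the
#' area of a fully censused circle yielding the same expected count. In
#' \eqn{(0, \pi(w^2 - l^2)]}.
#'
#' @inheritParams effective_strip_width
#' @export
effective_area <- function(spec, pars, z = NULL, w, left = 0) {
  Z <- z_matrix(z, length(spec$covariates),
                if (is.null(z) || is.null(dim(z))) 1L else nrow(as.matrix(z)))
  int_detfun(spec, pars, Z, w, left, weighted = TRUE)
}
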