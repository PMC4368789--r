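#' Finite half-normal mixture detection function
#'
#' Constructs the specification of a detection function built as a finite
#' mixture of half-normal components,
#' \deqn{g(y, z) = \sum_{j=1}^J \phi_j \exp\{-y^2 / 2\sigma_j(z)^2\},}
#' with mixture proportions \eqn{\phi_j > 0}, \eqn{\sum_j \phi_j = 1}, and a
#' log-linear covariate model on each component scale,
#' \eqn{\sigma_{ij} = \exp(\beta_{0j} + \sum_k \beta_k z_{ik})}. Covariates
#' shift all component scales by the same log-linear term; only the
#' intercepts \eqn{\beta_{0j}} differ between components. Because every
#' component is monotone non-increasing with \eqn{g_j(0) = 1}, the mixture is
#' automatically monotone non-increasing, non-negative, and equal to 1 at
#' zero distance for any parameter values — no constrained optimisation is
#' needed.
#'
#' The unconstrained parameter vector is laid out as
#' \code{c(beta0[1..J], beta[1..K], eta[1..J-1])} where \code{eta} maps to
#' the mixture proportions through a softmax with the last component as
#' fixed reference (see [mixture_weights()]).
#'
#' @param J number of mixture components (positive integer).
#' @param covariates character vector of covariate column names entering the
#'   log-scale linearly. Factors must be pre-expanded to indicator columns
#'   (see [ds_data()]).
#' @return an object of class \code{c("mix_spec", "detfun_spec")}.
#' @seealso [mix_hr()] for the hazard-rate-component variant used as a data
#'   generator, [ka_spec()] for the key-plus-adjustment baseline family.
#' @export
#' @examples
#' sp <- mix_hn(J = 2)
#' eval_detfun(sp, c(log(0.5), log(2), 0), y = c(0, 0.5, 1))
mix_hn <- function(J = 1, covariates = character(0)) {
  stopifnot(length(J) == 1, J >= 1, J == round(J))
  structure(list(family = "mix", component = "hn", J = as.integer(J),
                 covariates = as.character(covariates)),
            class = c("mix_spec", "detfun_spec"))
}

#' Finite hazard-rate mixture (data generator)
#'
#' A mixture of hazard-rate components
#' \eqn{g_j(y) = 1 - \exp\{-(y/\sigma_j)^{-b_j}\}} with shapes \eqn{b_j > 1}.
#' Used to generate data from detection shapes outside the half-normal
#' mixture class (scenario group E); it is not supported by [fit_ds()].
#' Parameter vector: \code{c(beta0[1..J], eta[1..J-1], log(b[1..J] - 1))}.
#'
#' @inheritParams mix_hn
#' @export
mix_hr <- function(J = 1, covariates = character(0)) {
  if (length(covariates)) stop("hazard-rate mixtures do not take covariates")
  structure(list(family = "mix", component = "hr", J = as.integer(J),
                 covariates = character(0)),
            class = c("mix_spec", "detfun_spec"))
}

#' Key-plus-adjustment detection function
#'
#' The conventional semiparametric detection function family: a parametric
#' key function \eqn{k} (half-normal, hazard-rate, or uniform) multiplied by
#' one plus a series \eqn{s} of even functions and standardised so that
#' \eqn{g(0, z) = 1}:
#' \deqn{g(y, z) = \frac{k(y, z)\{1 + s(y)\}}{k(0, z)\{1 + s(0)\}}.}
#' Adjustment arguments are scaled by the truncation distance \eqn{w}.
#' Cosine adjustments use terms \eqn{\cos(m\pi y/w)} starting at order 2 for
#' half-normal and hazard-rate keys (order 1 for the uniform key); simple
#' polynomials use even powers \eqn{(y/w)^{2m}} starting at order 4; Hermite
#' adjustments use even-order Hermite polynomials \eqn{H_{2m}(y/w)} starting
#' at order 4. Unlike the mixture family, adjusted functions can be
#' non-monotone or exceed \eqn{[0, 1]}; [fit_ds()] therefore imposes
#' monotonicity constraints on a distance grid during optimisation and
#' [check_monotone()] diagnoses violations.
#'
#' Parameter vector layout: key scale \code{log(sigma)} (absent for the
#' uniform key), covariate slopes, \code{log(shape - 1)} for the hazard-rate
#' key, then the adjustment coefficients in order.
#'
#' @param key key function, one of \code{"hn"}, \code{"hr"}, \code{"unif"}.
#' @param adjustment series type: \code{"none"}, \code{"cos"}, \code{"poly"}
#'   or \code{"herm"}.
#' @param nadj number of adjustment terms.
#' @param covariates covariate column names on the key log-scale (not
#'   allowed with a uniform key).
#' @return object of class \code{c("ka_spec", "detfun_spec")}.
#' @export
ka_spec <- function(key = c("hn", "hr", "unif"),
                    adjustment = c("none", "cos", "poly", "herm"),
                    nadj = 0L, covariates = character(0)) {
  key <- match.arg(key)
  adjustment <- match.arg(adjustment)
  nadj <- as.integer(nadj)
  if (adjustment == "none") nadj <- 0L
  if (nadj > 0L && adjustment == "none") stop("nadj > 0 needs an adjustment type")
  if (key == "unif" && length(covariates))
    stop("a uniform key cannot include covariates")
  if (key == "unif" && nadj == 0L)
    stop("a uniform key needs at least one adjustment term")
  structure(list(family = "ka", key = key, adjustment = adjustment,
                 nadj = nadj, covariates = as.character(covariates)),
            class = c("ka_spec", "detfun_spec"))
}

#' Number of free parameters of a detection-function specification
#' @param spec a \code{detfun_spec}.
#' @return integer parameter count.
#' @export
n_par <- function(spec) {
  K <- length(spec$covariates)
  if (inherits(spec, "eps_spec")) return(2L)
  if (inherits(spec, "mix_spec")) {
    J <- spec$J
    if (spec$component == "hn") J + K + (J - 1L) else J + (J - 1L) + J
  } else {
    nk <- switch(spec$key, hn = 1L + K, hr = 2L + K, unif = 0L)
    nk + spec$nadj
  }
}

#' Mixture proportions from unconstrained weight parameters
#'
#' Maps \eqn{J - 1} unconstrained reals onto the open simplex by a softmax
#' with the \eqn{J}th component as fixed zero reference:
#' \eqn{\phi_j = e^{\eta_j} / (1 + \sum_m e^{\eta_m})}, \eqn{\eta_J = 0}.
#' For \eqn{J = 2} this is the logistic map, and the all-zero parameter
#' point gives equal proportions for any \eqn{J}. The map is smooth,
#' invertible, and surjective onto the open simplex.
#'
#' @param weight_params numeric vector of length \eqn{J - 1} (length 0 gives
#'   the degenerate one-component simplex).
#' @return numeric vector of \eqn{J} proportions summing to one.
#' @export
#' @examples
#' mixture_weights(numeric(0))   # 1
#' mixture_weights(0)            # c(0.5, 0.5)
#' mixture_weights(c(0, 0))      # rep(1/3, 3)
mixture_weights <- function(weight_params) {
  if (length(weight_params) == 0) return(1)
  if (!all(is.finite(weight_params)))
    stop("weight parameters must be finite")
  x <- c(weight_params, 0)
  e <- exp(x - max(x))
  e / sum(e)
}

# inverse of mixture_weights (used when re-ordering fitted components)
weights_to_params <- function(phi) {
  if (length(phi) == 1) return(numeric(0))
  log(phi[-length(phi)] / phi[length(phi)])
}

# --- parameter decoding -----------------------------------------------------

decode_pars <- function(spec, pars) {
  if (length(pars) != n_par(spec))
    stop("parameter vector has length ", length(pars), ", expected ",
         n_par(spec))
  K <- length(spec$covariates)
  if (inherits(spec, "eps_spec"))
    return(list(sigma = exp(pars[1]), gamma = exp(pars[2])))
  if (inherits(spec, "mix_spec")) {
    J <- spec$J
    if (spec$component == "hn") {
      list(beta0 = pars[seq_len(J)],
           beta  = if (K) pars[J + seq_len(K)] else numeric(0),
           phi   = mixture_weights(pars[J + K + seq_len(J - 1)]),
           shape = NULL)
    } else {
      list(beta0 = pars[seq_len(J)],
           beta  = numeric(0),
           phi   = mixture_weights(pars[J + seq_len(J - 1)]),
           shape = 1 + exp(pars[2L * J - 1L + seq_len(J)]))
    }
  } else {
    i <- 0L
    sigma0 <- shape <- NULL
    beta <- numeric(0)
    if (spec$key %in% c("hn", "hr")) {
      sigma0 <- exp(pars[1L]); i <- 1L
      if (K) { beta <- pars[i + seq_len(K)]; i <- i + K }
      if (spec$key == "hr") { shape <- 1 + exp(pars[i + 1L]); i <- i + 1L }
    }
    list(sigma0 = sigma0, beta = beta, shape = shape,
         adj = if (spec$nadj) pars[i + seq_len(spec$nadj)] else numeric(0))
  }
}

# design-matrix handling: z may be NULL, a K-vector (one row), or an n x K
# matrix aligned with y
z_matrix <- function(z, K, n) {
  if (K == 0L) return(matrix(0, n, 0))
  if (is.null(z)) stop("covariate values required (", K, " columns)")
  if (is.null(dim(z))) {
    if (length(z) != K) stop("covariate length ", length(z),
                             " does not match model (", K, " columns)")
    z <- matrix(z, n, K, byrow = TRUE)
  }
  z <- as.matrix(z)
  if (ncol(z) != K) stop("covariate matrix has ", ncol(z),
                         " columns, expected ", K)
  if (nrow(z) == 1L && n > 1L) z <- z[rep(1L, n), , drop = FALSE]
  if (nrow(z) != n) stop("covariate rows do not match number of distances")
  z
}

# n x J matrix of per-observation component scales
scale_mat <- function(beta0, beta, Z) {
  lp <- if (length(beta)) as.vector(Z %*% beta) else rep(0, nrow(Z))
  exp(outer(lp, beta0, "+"))
}

#' Per-component scale parameter
#'
#' Evaluates \eqn{\sigma_{ij} = \exp(\beta_{0j} + \sum_k \beta_k z_{ik})}
#' for component \code{j} at covariate row \code{z}. Slopes are shared
#' across components; only the intercept depends on \code{j}.
#'
#' @param spec a \code{mix_spec}.
#' @param pars its parameter vector.
#' @param z covariate row (length-K numeric), or \code{NULL} with no
#'   covariates.
#' @param j component index in \code{1..J}.
#' @export
component_scale <- function(spec, pars, z = NULL, j = 1L) {
  stopifnot(inherits(spec, "mix_spec"), j >= 1, j <= spec$J)
  d <- decode_pars(spec, pars)
  Z <- z_matrix(z, length(spec$covariates), 1L)
  scale_mat(d$beta0, d$beta, Z)[1L, j]
}

# --- evaluation -------------------------------------------------------------

hn_kernel <- function(y, sigma) exp(-y^2 / (2 * sigma^2))
# hazard-rate: 1 - exp(-(y/sigma)^-b); at y = 0 the exponent is -Inf so g = 1
hr_kernel <- function(y, sigma, b) -expm1(-(y / sigma)^(-b))

# probabilists' Hermite polynomial by recurrence
hermite_poly <- function(m, x) {
  Hm1 <- rep(1, length(x)); H <- x
  if (m == 0) return(Hm1)
  for (k in seq_len(m - 1)) { Hn <- x * H - k * Hm1; Hm1 <- H; H <- Hn }
  H
}

adj_orders <- function(spec) {
  if (spec$nadj == 0L) return(integer(0))
  switch(spec$adjustment,
         cos  = (if (spec$key == "unif") 1L else 2L) + seq_len(spec$nadj) - 1L,
         poly = 2L * (1L + seq_len(spec$nadj)),      # powers 4, 6, 8, ...
         herm = 2L * (1L + seq_len(spec$nadj)))      # orders 4, 6, 8, ...
}

adj_series <- function(y, w, spec, coefs) {
  if (spec$nadj == 0L) return(rep(0, length(y)))
  ys <- y / w
  ord <- adj_orders(spec)
  s <- 0
  for (t in seq_along(ord)) {
    term <- switch(spec$adjustment,
                   cos  = cos(ord[t] * pi * ys),
                   poly = ys^ord[t],
                   herm = hermite_poly(ord[t], ys))
    s <- s + coefs[t] * term
  }
  s
}

#' Evaluate a detection function
#'
#' Computes \eqn{g(y, z)} for a mixture or key-plus-adjustment
#' specification. Mixture values always lie in \eqn{(0, 1]} with
#' \eqn{g(0, z) = 1}; key-plus-adjustment values are standardised to 1 at
#' zero distance but may fall outside \eqn{[0, 1]} for unconstrained
#' coefficients (no clamping is applied — diagnose with
#' [check_monotone()]).
#'
#' @param spec a \code{detfun_spec}.
#' @param pars parameter vector (see the spec constructors for layout).
#' @param y nonnegative distances.
#' @param z covariate row or matrix aligned with \code{y}; \code{NULL} when
#'   the model has no covariates.
#' @param w truncation distance; required for adjustment terms (their
#'   argument is \code{y/w}).
#' @return numeric vector of detection probabilities, one per distance.
#' @export
eval_detfun <- function(spec, pars, y, z = NULL, w = NULL) {
  if (any(y < 0)) stop("distances must be nonnegative")
  UseMethod("eval_detfun")
}

#' @export
eval_detfun.mix_spec <- function(spec, pars, y, z = NULL, w = NULL) {
  n <- length(y)
  d <- decode_pars(spec, pars)
  Z <- z_matrix(z, length(spec$covariates), n)
  sig <- scale_mat(d$beta0, d$beta, Z)
  comp <- if (spec$component == "hn") {
    hn_kernel(matrix(y, n, spec$J), sig)
  } else {
    kk <- matrix(0, n, spec$J)
    for (j in seq_len(spec$J)) kk[, j] <- hr_kernel(y, sig[1, j], d$shape[j])
    kk
  }
  as.vector(comp %*% d$phi)
}

#' @export
eval_detfun.ka_spec <- function(spec, pars, y, z = NULL, w = NULL) {
  n <- length(y)
  d <- decode_pars(spec, pars)
  if (spec$nadj > 0L && is.null(w))
    stop("w is required to evaluate adjustment terms")
  K <- length(spec$covariates)
  Z <- z_matrix(z, K, n)
  sigma <- if (spec$key == "unif") NULL else {
    lp <- if (K) as.vector(Z %*% d$beta) else rep(0, n)
    d$sigma0 * exp(lp)
  }
  kfun <- function(yy, sg) switch(spec$key,
    hn   = hn_kernel(yy, sg),
    hr   = hr_kernel(yy, sg, d$shape),
    unif = rep(1, length(yy)))
  ky <- kfun(y, sigma)
  k0 <- kfun(rep(0, n), sigma)
  sy <- 1 + adj_series(y, w %||% 1, spec, d$adj)
  s0 <- 1 + adj_series(rep(0, n), w %||% 1, spec, d$adj)
  den <- k0 * s0
  if (any(abs(den) < 1e-12))
    stop("degenerate standardization: k(0)(1 + s(0)) is numerically zero")
  ky * sy / den
}

#' Check monotonicity of a detection function on a distance grid
#'
#' Evaluates \eqn{g} at \code{M} equally spaced distances on \eqn{[0, w]}
#' and reports every index where the function increases by more than
#' \code{tol} or falls below \code{-tol}. Half-normal mixtures are monotone
#' non-increasing by construction and always pass; key-plus-adjustment fits
#' can fail, which is the motivating defect of that family.
#'
#' @inheritParams eval_detfun
#' @param M grid size (at least 2; default 20, the conventional default of
#'   the comparison software).
#' @param tol comparison tolerance.
#' @return list with elements \code{monotone} (logical) and
#'   \code{violations} (integer indices \code{i} where the step from grid
#'   point \code{i} to \code{i+1} violates the constraints).
#' @export
check_monotone <- function(spec, pars, z = NULL, w, M = 20L, tol = 1e-8) {
  stopifnot(M >= 2)
  ys <- seq(0, w, length.out = M)
  g <- eval_detfun(spec, pars, ys, z = z, w = w)
  bad <- which(g[-1] > g[-M] + tol | g[-1] < -tol)
  list(monotone = length(bad) == 0L, violations = bad)
}

#' @export
print.detfun_spec <- function(x, ...) {
  if (inherits(x, "mix_spec")) {
    cat(sprintf("%d-point %s mixture detection function\n", x$J,
                if (x$component == "hn") "half-normal" else "hazard-rate"))
  } else {
    lab <- c(hn = "half-normal", hr = "hazard-rate", unif = "uniform")[x$key]
    adj <- if (x$nadj == 0L) "no adjustments" else
      sprintf("%d %s adjustment term(s)", x$nadj, x$adjustment)
    cat(sprintf("%s key with %s\n", lab, adj))
  }
  if (length(x$covariates))
    cat("scale covariates:", paste(x$covariates, collapse = ", "), "\n")
  cat(n_par(x), "free parameters\n")
  invisible(x)
}
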