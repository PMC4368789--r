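#' Fit a candidate set of detection function models
#'
#' Fits half-normal mixtures with the requested numbers of components
#' directly, and key-plus-adjustment families by forward selection on the
#' number of adjustment terms: starting from zero terms, one more term is
#' added while the AIC keeps decreasing, up to \code{max_adjustments}.
#'
#' @param data a [ds_data()] object.
#' @param mixtures integer vector of mixture component counts (default
#'   \code{1:3}).
#' @param ka character vector of key+adjustment families as
#'   \code{"key+series"} strings, e.g. \code{c("hn+cos", "hr+poly")}; use
#'   \code{character(0)} for none.
#' @param max_adjustments cap on adjustment terms per K+A family.
#' @param covariates covariate column names included in every model's scale
#'   (raw names; factor columns are expanded automatically).
#' @param restarts,seed,control passed to [fit_ds()].
#' @param quiet suppress per-model failure messages.
#' @return list of \code{ds_fit} objects, each tagged with a \code{label}.
#' @export
fit_candidates <- function(data, mixtures = 1:3,
                           ka = c("hn+cos", "hr+poly"),
                           max_adjustments = 3L,
                           covariates = character(0),
                           restarts = 5L, seed = NULL, control = list(),
                           quiet = FALSE) {
  covs <- expand_covariates(data, covariates)
  fits <- list()
  for (J in mixtures) {
    lab <- sprintf("hn %d-pt mixture%s", J,
                   if (length(covs)) paste0(" + ", paste(covariates, collapse = "+")) else "")
    f <- try_fit(data, mix_hn(J, covariates = covs), restarts, seed, control,
                 lab, quiet)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  for (fam in ka) {
    parts <- strsplit(fam, "+", fixed = TRUE)[[1]]
    key <- parts[1]; series <- if (length(parts) > 1) parts[2] else "none"
    prev_aic <- Inf; best_prev <- NULL
    for (m in 0:max_adjustments) {
      if (m == 0L && key == "unif") next
      sp <- ka_spec(key = key,
                    adjustment = if (m == 0L) "none" else series,
                    nadj = m, covariates = covs)
      lab <- sprintf("%s+%s(%d)%s", key, series, m,
                     if (length(covs)) paste0(" ", paste(covariates, collapse = "+")) else "")
      f <- try_fit(data, sp, restarts, seed, control, lab, quiet)
      if (is.null(f)) break
      if (f$aic >= prev_aic) break  # forward selection: stop when AIC fails to decrease
      prev_aic <- f$aic; best_prev <- f
    }
    if (!is.null(best_prev)) fits[[length(fits) + 1L]] <- best_prev
  }
  fits
}

try_fit <- function(data, spec, restarts, seed, control, label, quiet) {
  f <- tryCatch(fit_ds(data, spec, restarts = restarts, seed = seed,
                       control = control),
                error = function(e) {
                  if (!quiet) message("fit failed for ", label, ": ",
                                      conditionMessage(e))
                  NULL
                })
  if (!is.null(f)) f$label <- label
  f
}

# map raw covariate names to design-matrix columns (factor expansion)
expand_covariates <- function(data, names) {
  if (!length(names)) return(character(0))
  cols <- colnames(data$Z)
  out <- character(0)
  for (nm in names) {
    if (nm %in% cols) { out <- c(out, nm); next }
    hit <- cols[startsWith(cols, nm)]
    if (!length(hit))
      stop("covariate '", nm, "' matches no data column")
    out <- c(out, hit)
  }
  unique(out)
}

#' Select the AIC-best detection function model
#'
#' Ranks converged candidate fits by AIC
#' (\eqn{\mathrm{AIC} = 2k - 2\ell}). Ties (within \code{1e-8}) are broken
#' in favour of fewer parameters, then mixtures before key-plus-adjustment
#' models.
#'
#' @param fits list of \code{ds_fit} objects (e.g. from
#'   [fit_candidates()]).
#' @return object of class \code{ds_modelset}: list with \code{fits}
#'   (sorted by AIC), \code{table} (label, family, npar, loglik, aic,
#'   delta_aic), and \code{best} (the winning \code{ds_fit}).
#' @export
select_aic <- function(fits) {
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("empty candidate set")
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(conv)) stop("no converged candidate")
  fits <- fits[conv]
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  npar <- vapply(fits, function(f) f$npar, numeric(1))
  fam <- vapply(fits, function(f)
    if (inherits(f$spec, "mix_spec")) 0L else 1L, integer(1))
  o <- order(round(aic / 1e-8) * 1e-8, npar, fam)
  fits <- fits[o]
  aic <- aic[o]
  tab <- data.frame(
    label = vapply(fits, function(f) f$label %||% class(f$spec)[1], ""),
    family = ifelse(fam[o] == 0L, "mixture", "K+A"),
    npar = npar[o],
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = aic,
    delta_aic = aic - min(aic),
    monotone = vapply(fits, function(f) f$monotone, logical(1)),
    row.names = NULL)
  structure(list(fits = fits, table = tab, best = fits[[1L]]),
            class = "ds_modelset")
}

#' @export
print.ds_modelset <- function(x, ...) {
  cat("detection function model comparison (AIC-best first):\n")
  print(x$table, digits = 6)
  invisible(x)
}

#' Model comparison table with abundance and GOF summaries
#'
#' One row per candidate: model label, \eqn{\Delta}AIC, \eqn{\hat P_a},
#' percent CV of \eqn{\hat P_a}, and Kolmogorov-Smirnov p-value. Optionally
#' written to a delimited text file.
#'
#' @param modelset a \code{ds_modelset} from [select_aic()].
#' @param file optional path to write the table as CSV.
#' @return the data.frame, invisibly when written to file.
#' @export
results_table <- function(modelset, file = NULL) {
  stopifnot(inherits(modelset, "ds_modelset"))
  rows <- lapply(modelset$fits, function(f) {
    ab <- tryCatch(abundance(f), error = function(e) NULL)
    ks <- tryCatch(gof_ks(f), error = function(e) list(p_value = NA_real_))
    p <- p_per_obs(f)
    data.frame(model = f$label %||% "model",
               delta_aic = f$aic - modelset$best$aic,
               P_a = if (!is.null(ab)) ab$P_a_hat else length(p) / sum(1 / p),
               cv_P_a = if (!is.null(ab)) ab$cv_P_a else NA_real_,
               ks_p = ks$p_value)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(file)) {
    utils::write.csv(tab, file, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
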