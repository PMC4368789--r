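#' Distance sampling survey data
#'
#' Bundles detection distances with covariates and survey geometry into a
#' validated container used by [fit_ds()]. Factor covariates are expanded to
#' treatment-contrast indicator columns (reference level = first level in
#' lexicographic order, which carries no column), so the model design matrix
#' is fixed and reproducible.
#'
#' @param distances numeric vector of perpendicular (line) or radial (point)
#'   detection distances, all in \code{[left, w]}.
#' @param covariates optional data.frame of covariate columns aligned with
#'   \code{distances}. Character columns must be declared factors by the
#'   caller (e.g. via [read_survey()]'s \code{factors} argument); they are
#'   never guessed.
#' @param transect survey geometry, \code{"line"} or \code{"point"}. The
#'   distance distribution of available objects is uniform \eqn{1/w} for
#'   lines and triangular \eqn{2y/w^2} for points.
#' @param w truncation distance (maximum recorded distance).
#' @param left left-truncation distance below which objects are not
#'   recorded; default 0.
#' @param cutpoints optional strictly increasing bin edges for grouped
#'   (binned) distances, starting at \code{left} and ending at \code{w}.
#'   Intervals are half-open \code{[c_l, c_{l+1})}, the last closed at
#'   \code{w}.
#' @param effort total line length \eqn{L} (lines) or number of visited
#'   points \eqn{k} (points); needed for abundance estimation.
#' @param area study area \eqn{A}; defaults to the covered area \eqn{a}
#'   when missing.
#' @param transect_id optional transect identifier per observation, enabling
#'   the encounter-rate variance component.
#' @param transect_effort optional named vector of per-transect effort
#'   (line lengths), names matching \code{transect_id} levels. Defaults to
#'   equal split of \code{effort} over the observed transects.
#' @return object of class \code{ds_data}.
#' @export
ds_data <- function(distances, covariates = NULL,
                    transect = c("line", "point"), w,
                    left = 0, cutpoints = NULL,
                    effort = NULL, area = NULL,
                    transect_id = NULL, transect_effort = NULL) {
  transect <- match.arg(transect)
  distances <- as.numeric(distances)
  if (length(distances) < 1L) stop("at least one observation is required")
  if (any(!is.finite(distances)) || any(distances < 0))
    stop("distances must be finite and nonnegative")
  if (left < 0 || left >= w) stop("need 0 <= left < w")
  if (any(distances < left) || any(distances > w))
    stop("all distances must lie in [left, w]; truncate first (see read_survey)")
  if (transect == "point" && left == 0 && any(distances == 0))
    stop("degenerate observation: radial distance 0 has zero density at a point")

  bin <- NULL
  if (!is.null(cutpoints)) {
    cutpoints <- as.numeric(cutpoints)
    if (length(cutpoints) < 2L || any(diff(cutpoints) <= 0))
      stop("cutpoints must be strictly increasing with at least two edges")
    if (abs(cutpoints[1] - left) > 1e-12 ||
        abs(cutpoints[length(cutpoints)] - w) > 1e-12)
      stop("cutpoints must start at left and end at w")
    bin <- findInterval(distances, cutpoints, rightmost.closed = TRUE)
  }

  Z <- matrix(0, length(distances), 0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(distances))
      stop("covariates must have one row per observation")
    for (nm in names(covariates)) {
      cl <- covariates[[nm]]
      if (is.character(cl))
        stop("character column '", nm, "' must be declared as a factor")
    }
    if (ncol(covariates)) {
      # treatment contrasts, reference = first lexicographic level
      cov2 <- covariates
      for (nm in names(cov2)) if (is.factor(cov2[[nm]]))
        cov2[[nm]] <- factor(cov2[[nm]], levels = sort(levels(cov2[[nm]])))
      mf <- stats::model.matrix(~ ., data = cov2)
      Z <- mf[, -1, drop = FALSE]
    }
  }

  if (!is.null(transect_id)) {
    transect_id <- as.character(transect_id)
    if (length(transect_id) != length(distances))
      stop("transect_id must have one value per observation")
  }

  structure(list(distances = distances, covariates = covariates, Z = Z,
                 transect = transect, w = w, left = left,
                 cutpoints = cutpoints, bin = bin,
                 effort = effort, area = area,
                 transect_id = transect_id,
                 transect_effort = transect_effort),
            class = "ds_data")
}

#' @export
print.ds_data <- function(x, ...) {
  cat(sprintf("%s transect survey: %d observations, w = %g%s\n",
              x$transect, length(x$distances), x$w,
              if (x$left > 0) sprintf(", left = %g", x$left) else ""))
  if (!is.null(x$cutpoints))
    cat("binned into", length(x$cutpoints) - 1L, "intervals\n")
  if (ncol(x$Z))
    cat("covariate columns:", paste(colnames(x$Z), collapse = ", "), "\n")
  invisible(x)
}

# resolve a spec's covariate names against the data design matrix
spec_design <- function(spec, data) {
  K <- length(spec$covariates)
  if (K == 0L) return(matrix(0, length(data$distances), 0))
  miss <- setdiff(spec$covariates, colnames(data$Z))
  if (length(miss))
    stop("covariates not in data: ", paste(miss, collapse = ", "),
         " (available: ", paste(colnames(data$Z), collapse = ", "), ")")
  data$Z[, spec$covariates, drop = FALSE]
}
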