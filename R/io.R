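#' Read survey data from a delimited text file
#'
#' Reads one row per detection, validates, applies right truncation at
#' \code{w} (and left truncation at \code{left}) with a logged count of
#' excluded rows — truncation distances may legitimately be chosen after
#' the survey. Unknown columns are preserved in the returned object's
#' \code{covariates} only when declared; they are never guessed. Factor
#' columns must be declared through \code{factors}.
#'
#' @param path file path.
#' @param w truncation distance.
#' @param transect \code{"line"} or \code{"point"}.
#' @param delimiter field separator (default comma).
#' @param distance_col name of the distance column.
#' @param covariates character vector of covariate column names to carry.
#' @param factors subset of \code{covariates} to treat as factors.
#' @param left left-truncation distance.
#' @param cutpoints optional bin edges for grouped data.
#' @param effort total line length L or number of points k.
#' @param area study area A.
#' @param transect_id_col optional column with transect identifiers.
#' @param quiet suppress the truncation log message.
#' @return a [ds_data()] object.
#' @export
read_survey <- function(path, w, transect = c("line", "point"),
                        delimiter = ",", distance_col = "distance",
                        covariates = character(0), factors = character(0),
                        left = 0, cutpoints = NULL, effort = NULL,
                        area = NULL, transect_id_col = NULL, quiet = FALSE) {
  transect <- match.arg(transect)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE)
  if (!distance_col %in% names(df))
    stop("missing distance column '", distance_col, "' in ", path)
  y <- df[[distance_col]]
  if (!is.numeric(y) || any(!is.finite(y)))
    stop("distance column must be numeric and finite")
  if (any(y < 0)) stop("negative distances in ", path)
  if (left >= w) stop("need left < w")
  keep <- y >= left & y <= w
  if (!quiet && any(!keep))
    message(sum(!keep), " of ", length(y),
            " observations outside [", left, ", ", w, "] removed by truncation")
  if (!any(keep)) stop("no observations remain after truncation")
  df <- df[keep, , drop = FALSE]
  miss <- setdiff(covariates, names(df))
  if (length(miss)) stop("declared covariates not in file: ",
                         paste(miss, collapse = ", "))
  covs <- if (length(covariates)) df[covariates] else NULL
  if (!is.null(covs)) for (nm in factors) covs[[nm]] <- factor(covs[[nm]])
  tid <- if (!is.null(transect_id_col)) {
    if (!transect_id_col %in% names(df))
      stop("transect id column '", transect_id_col, "' not in file")
    df[[transect_id_col]]
  } else NULL
  ds_data(df[[distance_col]], covariates = covs, transect = transect,
          w = w, left = left, cutpoints = cutpoints, effort = effort,
          area = area, transect_id = tid)
}

#' Write survey data to a delimited text file
#'
#' Inverse of [read_survey()]: distances (full precision), covariates and
#' transect ids, one row per detection. Round-trips bit-exactly.
#'
#' @param data a [ds_data()] object.
#' @param path output path.
#' @param delimiter field separator.
#' @export
write_survey <- function(data, path, delimiter = ",") {
  df <- data.frame(distance = data$distances)
  if (!is.null(data$covariates)) df <- cbind(df, data$covariates)
  if (!is.null(data$transect_id)) df$transect_id <- data$transect_id
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = delimiter, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate the test fixture datasets
#'
#' Writes small seeded survey files used by the test-suite, each with a
#' sidecar \code{*.truth.json}-style text file recording the generating
#' model, its parameters, the seed and the true average detectability.
#' Fixtures: a 1-point half-normal line survey, a strongly spiked 2-point
#' line survey (at least 40 percent of distances below \eqn{0.1 w} by
#' construction of the generator), a 2-point point-transect survey, a line
#' survey with a binary covariate, and a binned line survey.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; fixtures regenerate identically from it.
#' @return invisibly, the vector of file paths written.
#' @export
make_fixtures <- function(dir, seed = 20150320L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(name, y, covs = NULL, truth) {
    p <- file.path(dir, paste0(name, ".csv"))
    df <- data.frame(distance = y)
    if (!is.null(covs)) df <- cbind(df, covs)
    utils::write.table(format(df, digits = 17, trim = TRUE), p, sep = ",",
                       row.names = FALSE, quote = FALSE)
    writeLines(truth, file.path(dir, paste0(name, ".truth.txt")))
    paths <<- c(paths, p)
  }
  set.seed(seed)
  g1 <- generator("hn-mix", phi = 1, sigma = 0.45)
  put("line-hn1", sample_line_distances(gen_fun(g1), 80, 1),
      truth = c("family: hn-mix J=1", "sigma: 0.45", "w: 1",
                "transect: line", paste("seed:", seed)))
  gs <- generator("hn-mix", phi = c(0.92, 0.08), sigma = c(0.025, 0.5))
  put("line-spiked", sample_line_distances(gen_fun(gs), 120, 1),
      truth = c("family: hn-mix J=2", "phi: 0.92 0.08", "sigma: 0.025 0.5",
                "w: 1", "transect: line", paste("seed:", seed)))
  gp <- generator("hn-mix", phi = c(0.4, 0.6), sigma = c(0.2, 0.7))
  put("point-hn2", sample_point_distances(gen_fun(gp), 100, 1),
      truth = c("family: hn-mix J=2", "phi: 0.4 0.6", "sigma: 0.2 0.7",
                "w: 1", "transect: point", paste("seed:", seed)))
  gd <- generator("hn-mix", phi = c(0.4, 0.6), sigma = c(0.15, 0.6),
                  beta = 0.7, covariates = "grp")
  zf <- factor(rep(c("a", "b"), length.out = 100))
  zi <- as.numeric(zf == "b")
  yd <- vapply(zi, function(z)
    sample_line_distances(function(y) eval_detfun(gd$spec, gd$pars, y, z = z),
                          1L, 1), numeric(1))
  put("line-covariate", yd, covs = data.frame(grp = zf),
      truth = c("family: hn-mix J=2 + binary covariate", "phi: 0.4 0.6",
                "sigma: 0.15 0.6", "beta: 0.7", "w: 1", "transect: line",
                paste("seed:", seed)))
  gb <- generator("hn-mix", phi = 1, sigma = 0.5)
  yb <- sample_line_distances(gen_fun(gb), 150, 1)
  cp <- seq(0, 1, by = 0.125)
  put("line-binned", yb,
      truth = c("family: hn-mix J=1", "sigma: 0.5", "w: 1",
                paste("cutpoints:", paste(cp, collapse = " ")),
                "transect: line", paste("seed:", seed)))
  invisible(paths)
}
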