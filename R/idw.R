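#' IDW interpolation parameters
#'
#' The inverse-distance-weighting prediction at location \eqn{x_0} is
#' \deqn{Z^*(x_0) = \sum_{i=1}^{N} \lambda_i Z(x_i), \qquad
#'       \lambda_i = \frac{d_{i0}^{-p}}{\sum_j d_{j0}^{-p}}}
#' over the N nearest measured points.  Weights sum to one, so predictions
#' lie in the convex hull of the neighbour values, and a query coinciding
#' with a measured point returns that measurement (exact interpolator).
#'
#' @param power distance exponent p (> 0); p = 1 or 2 are conventional,
#'   default 2.
#' @param nNeighbors number of nearest neighbours per prediction (0 = use
#'   all points; default 12).
#' @param maxSearchRadiusM search radius in metres (default unlimited).
#' @param zeroTolM distance below which a query is treated as coincident
#'   with a measured point (default 1e-9 m).
#' @return object of class `idwParams`.
#' @export
idwParams <- function(power = 2, nNeighbors = 12L, maxSearchRadiusM = Inf,
                      zeroTolM = 1e-9) {
  if (power <= 0) stop("power must be > 0")
  if (nNeighbors < 0) stop("nNeighbors must be >= 0")
  structure(list(power = power, nNeighbors = as.integer(nNeighbors),
                 maxSearchRadiusM = maxSearchRadiusM, zeroTolM = zeroTolM),
            class = "idwParams")
}

## shared entry: predict a matrix of variables at arbitrary locations
idwAt <- function(x, y, measured, variables, params) {
  stopifnot(inherits(params, "idwParams"))
  if (!nrow(measured)) stop("invalid input: empty measured table")
  miss <- setdiff(variables, names(measured))
  if (length(miss)) stop("variables not in table: ",
                         paste(miss, collapse = ", "))
  vals <- as.matrix(measured[variables])
  storage.mode(vals) <- "double"
  tie <- if ("shot_id" %in% names(measured))
    as.integer(measured$shot_id) else seq_len(nrow(measured))
  out <- .idwCore(as.numeric(x), as.numeric(y),
                  as.numeric(measured$x), as.numeric(measured$y),
                  vals, tie, params$power, params$nNeighbors,
                  params$maxSearchRadiusM, params$zeroTolM)
  colnames(out) <- variables
  out
}

#' IDW prediction at point locations
#'
#' @param x,y numeric vectors of query coordinates (m).
#' @param measured footprint data.frame with `x`, `y` and the variable.
#' @param variable metric column to interpolate.
#' @param params an [idwParams()].
#' @return numeric vector of predictions; `NA` where no measured point
#'   lies within the search radius.
#' @examples
#' pts <- data.frame(shot_id = 1:3, x = c(1, 2, 4), y = 0,
#'                   v = c(0, 6, 12))
#' idwPredict(0, 0, pts, "v", idwParams(nNeighbors = 0))  # 12/7
#' @export
idwPredict <- function(x, y, measured, variable, params = idwParams()) {
  as.numeric(idwAt(x, y, measured, variable, params))
}

#' IDW interpolation of footprint metrics to a regular grid
#'
#' Predicts every cell centre of the requested grid by IDW from the
#' measured footprints.  Cells with no neighbour in the search radius are
#' nodata.  Several variables can be rasterised in one pass; the neighbour
#' search is shared across variables.
#'
#' @param measured footprint data.frame.
#' @param variables metric column name(s) to interpolate.
#' @param extent named `c(xmin, xmax, ymin, ymax)` of the output grid (m).
#' @param resolutionM cell size (m), default 30.
#' @param params an [idwParams()].
#' @return a [RasterGrid-class] for a single variable, otherwise a named
#'   list of them.
#' @export
idwRasterize <- function(measured, variables, extent, resolutionM = 30,
                         params = idwParams()) {
  extent <- checkExtent(extent)
  if (resolutionM <= 0) stop("resolutionM must be > 0")
  nc <- max(1L, ceiling((extent["xmax"] - extent["xmin"]) / resolutionM))
  nr <- max(1L, ceiling((extent["ymax"] - extent["ymin"]) / resolutionM))
  col <- rep(seq_len(nc), times = nr)
  row <- rep(seq_len(nr), each = nc)
  cx <- extent["xmin"] + (col - 0.5) * resolutionM
  cy <- extent["ymax"] - (row - 0.5) * resolutionM
  pred <- idwAt(cx, cy, measured, variables, params)
  grids <- lapply(seq_along(variables), function(v) {
    m <- matrix(pred[, v], nr, nc, byrow = TRUE)
    rasterGrid(m, extent["xmin"], extent["ymax"], resolutionM)
  })
  names(grids) <- variables
  if (length(variables) == 1L) grids[[1L]] else grids
}

#' Seeded random train/validation split
#'
#' Disjoint, exhaustive uniform random partition of the footprint records,
#' e.g. 70% for interpolation and 30% held out for accuracy evaluation.
#'
#' @param table footprint data.frame (>= 2 rows).
#' @param fraction training fraction in (0, 1), default 0.7.
#' @param seed integer seed.
#' @return list with `train` and `validation` data.frames.
#' @export
splitTrainValidation <- function(table, fraction = 0.7, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  n <- nrow(table)
  if (n < 2L) stop("invalid input: need at least 2 records to split")
  set.seed(seed)
  idx <- sample.int(n, size = round(fraction * n))
  train <- table[idx, , drop = FALSE]
  validation <- table[-idx, , drop = FALSE]
  rownames(train) <- rownames(validation) <- NULL
  list(train = train, validation = validation)
}

#' Accuracy metrics between observed and predicted values
#'
#' \deqn{R^2 = 1 - \frac{\sum (\hat y_i - y_i)^2}{\sum (y_i - \bar y)^2},
#'  \quad RMSE = \sqrt{\tfrac{1}{n}\sum(\hat y_i - y_i)^2},
#'  \quad MAE = \tfrac{1}{n}\sum |\hat y_i - y_i|}
#' `NA` predictions are excluded and counted in `n_nodata`.  With constant
#' observations the R2 denominator is zero: `r2` is `NA` and
#' `r2_defined` is `FALSE` (flagged, not silently propagated).
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return list of class `evalMetrics`: `r2`, `rmse`, `mae`, `n`,
#'   `n_nodata`, `r2_defined`.
#' @examples
#' evalMetrics(c(1, 2, 3), c(2, 2, 2))  # rmse 0.8165, mae 0.6667, r2 0
#' @export
evalMetrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ok <- is.finite(observed) & is.finite(predicted)
  nNodata <- sum(is.finite(observed) & !is.finite(predicted))
  y <- observed[ok]
  yhat <- predicted[ok]
  n <- length(y)
  if (n == 0L) stop("evaluation error: no valid (observed, predicted) pairs")
  sse <- sum((yhat - y)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  structure(list(r2 = r2, rmse = sqrt(sse / n), mae = mean(abs(yhat - y)),
                 n = n, n_nodata = nNodata, r2_defined = sst > 0),
            class = "evalMetrics")
}

#' Evaluate IDW interpolation accuracy on held-out footprints
#'
#' Interpolates a variable from the training footprints at the validation
#' footprint locations (validation points are never interpolation sources)
#' and compares predictions with the held-out measurements.
#'
#' @param train,validation footprint data.frames.
#' @param variable metric column to evaluate.
#' @param params an [idwParams()].
#' @return an [evalMetrics()] result.
#' @export
evaluateInterpolation <- function(train, validation, variable,
                                  params = idwParams()) {
  if (!nrow(validation)) stop("invalid input: empty validation set")
  pred <- idwPredict(validation$x, validation$y, train, variable, params)
  if (all(!is.finite(pred))) {
    stop("evaluation error: all predictions are nodata")
  }
  evalMetrics(validation[[variable]], pred)
}

#' Footprint-density sensitivity experiment
#'
#' For each thinning interval k: thin the footprints to every k-th shot,
#' split the retained shots into train/validation, interpolate every
#' variable from the training part at the validation locations, and
#' record R2, RMSE and MAE.  This quantifies how interpolation accuracy
#' responds to footprint sampling density.
#'
#' @param table filtered footprint data.frame.
#' @param intervals integer thinning intervals, e.g. `c(10, 30, 50, 70,
#'   100)`.
#' @param variables metric columns to evaluate (default all 14).
#' @param fraction training fraction (default 0.7).
#' @param params an [idwParams()].
#' @param seed integer seed (drives the splits).
#' @param perBeam thin per beam line (default) or pooled.
#' @return data.frame of class `densityExperiment` with one row per
#'   (interval, variable): `interval`, `variable`, `n_train`, `n_valid`,
#'   `n_nodata`, `r2`, `rmse`, `mae`; the split fraction and seed are
#'   attached as attributes.
#' @export
runDensityExperiment <- function(table, intervals = c(10, 30, 50, 70, 100),
                                 variables = gediMetricNames(),
                                 fraction = 0.7, params = idwParams(),
                                 seed = 1L, perBeam = TRUE) {
  if (any(intervals < 1)) stop("intervals must be >= 1")
  rows <- list()
  for (k in intervals) {
    thin <- thinFootprints(table, k, perBeam = perBeam)
    sp <- splitTrainValidation(thin, fraction, seed = seed + as.integer(k))
    pred <- idwAt(sp$validation$x, sp$validation$y, sp$train, variables,
                  params)
    for (v in variables) {
      m <- tryCatch(evalMetrics(sp$validation[[v]], pred[, v]),
                    error = function(e) {
                      stop("density experiment failed at interval ", k,
                           ", variable ", v, ": ", conditionMessage(e))
                    })
      rows[[length(rows) + 1L]] <- data.frame(
        interval = k, variable = v, n_train = nrow(sp$train),
        n_valid = m$n, n_nodata = m$n_nodata,
        r2 = m$r2, rmse = m$rmse, mae = m$mae)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fraction") <- fraction
  attr(out, "seed") <- seed
  class(out) <- c("densityExperiment", "data.frame")
  out
}

#' Write a density-experiment result as CSV and/or JSON
#' @param result a [runDensityExperiment()] result.
#' @param csvPath,jsonPath output paths (`NULL` to skip either).
#' @return invisibly, the paths written.
#' @export
writeDensityExperiment <- function(result, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath)) {
    utils::write.csv(as.data.frame(result), csvPath, row.names = FALSE)
  }
  if (!is.null(jsonPath)) {
    jsonlite::write_json(list(fraction = attr(result, "fraction"),
                              seed = attr(result, "seed"),
                              results = as.data.frame(result)),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csvPath, jsonPath))
}
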