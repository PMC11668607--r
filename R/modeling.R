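#' Extract interpolated metric values at plot locations
#'
#' Builds the feature matrix for biomass modelling: one row per plot, one
#' column per interpolated surface, the value being that of the raster
#' cell *containing* the plot centre (matching the cell semantics of an
#' IDW surface; no resampling).  Plots outside the raster extent or on
#' nodata cells are excluded with a warning and listed in the
#' `"exclusionReport"` attribute.
#'
#' @param plots data.frame with `plot_id`, `x`, `y`, `agb_t_hm2`.
#' @param rasters named list of aligned [RasterGrid-class] surfaces.
#' @return data.frame with `plot_id`, one column per raster, and the
#'   response `agb_t_hm2`.
#' @export
extractFeatures <- function(plots, rasters) {
  stopifnot(all(c("plot_id", "x", "y", "agb_t_hm2") %in% names(plots)),
            length(rasters) >= 1L, !is.null(names(rasters)))
  fm <- data.frame(plot_id = plots$plot_id)
  for (v in names(rasters)) {
    fm[[v]] <- valueAtXY(rasters[[v]], plots$x, plots$y)
  }
  fm$agb_t_hm2 <- plots$agb_t_hm2
  bad <- !stats::complete.cases(fm[names(rasters)])
  if (any(bad)) {
    warning(sum(bad), " plot(s) outside the raster extent or on nodata ",
            "cells were excluded")
  }
  out <- fm[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusionReport") <- list(
    n_input = nrow(plots), n_kept = nrow(out),
    excluded_plot_ids = plots$plot_id[bad])
  out
}

#' Rank features by correlation with plot biomass
#'
#' Pearson correlation of each feature with the AGB response, with
#' two-sided significance marks at the 0.05 and 0.01 levels, ranked by
#' absolute correlation.  Zero-variance features have undefined r; they
#' are flagged and ranked last.
#'
#' @param fm feature matrix from [extractFeatures()] (>= 3 complete rows).
#' @param topK number of top-ranked features to flag as selected
#'   (default 5).
#' @return data.frame with `variable`, `r`, `p_value`, `significance`
#'   (`"**"`, `"*"` or `""`), `defined`, `rank`, `selected`, ordered by
#'   rank.
#' @export
correlationScreen <- function(fm, topK = 5L) {
  vars <- setdiff(names(fm), c("plot_id", "agb_t_hm2"))
  if (nrow(fm) < 3L) stop("need at least 3 complete rows for screening")
  y <- fm$agb_t_hm2
  res <- lapply(vars, function(v) {
    x <- fm[[v]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(variable = v, r = NA_real_, p_value = NA_real_,
                        significance = "", defined = FALSE))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(variable = v, r = unname(ct$estimate),
               p_value = ct$p.value,
               significance = if (ct$p.value < 0.01) "**" else
                 if (ct$p.value < 0.05) "*" else "",
               defined = TRUE)
  })
  out <- do.call(rbind, res)
  ord <- order(!out$defined, -abs(out$r), na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$selected <- out$rank <= topK & out$defined
  rownames(out) <- NULL
  out
}

#' Configuration of a biomass estimator
#'
#' Hyperparameters follow the study defaults: random forest with 300
#' trees and `mtry = 2`; support vector regression with a radial-basis
#' kernel, cost 1 and gamma 0.92; k-nearest-neighbour regression with
#' k = 9.
#'
#' @param algorithm `"rf"`, `"svm"` or `"knn"`.
#' @param ntree,mtry random-forest parameters.
#' @param cost,gamma radial-basis SVM parameters.
#' @param k KNN neighbour count.
#' @param seed integer seed used for fold assignment and stochastic fits.
#' @return object of class `modelConfig`.
#' @export
modelConfig <- function(algorithm = c("rf", "svm", "knn"), ntree = 300L,
                        mtry = 2L, cost = 1, gamma = 0.92, k = 9L,
                        seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (ntree <= 0 || mtry <= 0 || cost <= 0 || gamma <= 0 || k <= 0) {
    stop("configuration error: hyperparameters must be positive")
  }
  structure(list(algorithm = algorithm, ntree = as.integer(ntree),
                 mtry = as.integer(mtry), cost = cost, gamma = gamma,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "modelConfig")
}

fitEstimator <- function(x, y, config) {
  switch(config$algorithm,
    rf = randomForest::randomForest(x = x, y = y, ntree = config$ntree,
                                    mtry = min(config$mtry, ncol(x))),
    svm = e1071::svm(x = x, y = y, type = "eps-regression",
                     kernel = "radial", cost = config$cost,
                     gamma = config$gamma),
    knn = caret::knnreg(x = x, y = y, k = config$k),
    stop("configuration error: unsupported algorithm ", config$algorithm))
}

predictEstimator <- function(fit, x) {
  as.numeric(stats::predict(fit, x))
}

#' Fit a biomass model under k-fold cross-validation
#'
#' Plots are assigned to `nFolds` folds by a seeded random permutation
#' (simple random, plot-level).  Each fold is held out in turn, the model
#' is trained on the rest, and R2/RMSE/MAE are computed on the held-out
#' predictions; the reported summary is the mean over folds, alongside
#' metrics pooled over all out-of-fold predictions.  A final model is
#' refit on all rows for mapping.
#'
#' @param fm feature matrix from [extractFeatures()].
#' @param variables feature columns to use (e.g. the top-5 screened).
#' @param config a [modelConfig()].
#' @param nFolds number of folds (default 10).
#' @return list of class `cvResult`: `fold_metrics` (one row per fold),
#'   `mean_metrics`, `pooled_metrics`, `oof_predictions` (per plot),
#'   `folds`, `model`, `config`, `variables`, `train_range`.
#' @export
fitAndCrossValidate <- function(fm, variables, config = modelConfig("rf"),
                                nFolds = 10L) {
  stopifnot(inherits(config, "modelConfig"))
  miss <- setdiff(variables, names(fm))
  if (length(miss)) stop("variables not in feature matrix: ",
                         paste(miss, collapse = ", "))
  n <- nrow(fm)
  if (n < nFolds) stop("need at least nFolds rows")
  x <- as.matrix(fm[variables])
  y <- fm$agb_t_hm2
  set.seed(config$seed)
  folds <- sample(rep(seq_len(nFolds), length.out = n))
  oof <- rep(NA_real_, n)
  foldRows <- vector("list", nFolds)
  for (f in seq_len(nFolds)) {
    hold <- folds == f
    set.seed((as.numeric(config$seed) * 1000 + f) %% 2147483647)
    fit <- fitEstimator(x[!hold, , drop = FALSE], y[!hold], config)
    oof[hold] <- predictEstimator(fit, x[hold, , drop = FALSE])
    m <- evalMetrics(y[hold], oof[hold])
    foldRows[[f]] <- data.frame(fold = f, n = m$n, r2 = m$r2,
                                rmse = m$rmse, mae = m$mae,
                                r2_defined = m$r2_defined)
  }
  foldMetrics <- do.call(rbind, foldRows)
  meanMetrics <- list(r2 = mean(foldMetrics$r2[foldMetrics$r2_defined]),
                      rmse = mean(foldMetrics$rmse),
                      mae = mean(foldMetrics$mae))
  set.seed((as.numeric(config$seed) * 1000) %% 2147483647)
  finalFit <- fitEstimator(x, y, config)
  structure(list(fold_metrics = foldMetrics, mean_metrics = meanMetrics,
                 pooled_metrics = evalMetrics(y, oof),
                 oof_predictions = data.frame(plot_id = fm$plot_id,
                                              observed = y,
                                              predicted = oof,
                                              fold = folds),
                 folds = folds, model = finalFit, config = config,
                 variables = variables,
                 train_range = range(y)),
            class = "cvResult")
}

#' @export
print.cvResult <- function(x, ...) {
  cat(sprintf("cvResult: %s, %d folds, %d plots, features: %s\n",
              x$config$algorithm, nrow(x$fold_metrics),
              nrow(x$oof_predictions),
              paste(x$variables, collapse = ", ")))
  cat(sprintf("  mean over folds:  R2 %.3f, RMSE %.2f, MAE %.2f\n",
              x$mean_metrics$r2, x$mean_metrics$rmse, x$mean_metrics$mae))
  p <- x$pooled_metrics
  cat(sprintf("  pooled out-of-fold: R2 %.3f, RMSE %.2f, MAE %.2f\n",
              p$r2, p$rmse, p$mae))
  invisible(x)
}

#' Wall-to-wall biomass map from a fitted model
#'
#' Predicts AGB for every raster cell where all selected feature surfaces
#' are valid; other cells are nodata.  The summary reports min, max and
#' mean density (t/hm^2), the mapped cell count, and the total biomass
#' (mean density x mapped area) in units of 10^4 t.
#'
#' @param cv a [fitAndCrossValidate()] result (its final model is used).
#' @param rasters named list of aligned [RasterGrid-class] surfaces
#'   containing at least the model's variables.
#' @param mask optional `RasterGrid` aligned with the features; cells
#'   where the mask is `NA` or 0 are excluded (e.g. a forest-type mask).
#' @return list with `map` (a `RasterGrid`) and `summary` (min, max,
#'   mean, total_1e4_t, n_cells, cell_size_m).
#' @export
predictMap <- function(cv, rasters, mask = NULL) {
  stopifnot(inherits(cv, "cvResult"))
  miss <- setdiff(cv$variables, names(rasters))
  if (length(miss)) stop("rasters missing model variables: ",
                         paste(miss, collapse = ", "))
  ref <- rasters[[cv$variables[1L]]]
  d <- dim(ref)
  for (v in cv$variables) {
    g <- rasters[[v]]
    if (!identical(dim(g), d) || g@originX != ref@originX ||
        g@originY != ref@originY || g@cellSize != ref@cellSize) {
      stop("alignment error: raster grids are not aligned for ", v)
    }
  }
  feat <- vapply(cv$variables,
                 function(v) as.numeric(t(gridValues(rasters[[v]]))),
                 numeric(prod(d)))
  feat <- matrix(feat, ncol = length(cv$variables),
                 dimnames = list(NULL, cv$variables))
  ok <- stats::complete.cases(feat)
  if (!is.null(mask)) {
    if (!identical(dim(mask), d)) stop("alignment error: mask not aligned")
    mv <- as.numeric(t(gridValues(mask)))
    ok <- ok & is.finite(mv) & mv != 0
  }
  pred <- rep(NA_real_, nrow(feat))
  if (any(ok)) {
    pred[ok] <- predictEstimator(cv$model, feat[ok, , drop = FALSE])
  }
  map <- rasterGrid(matrix(pred, d[1], d[2], byrow = TRUE),
                    ref@originX, ref@originY, ref@cellSize)
  v <- pred[is.finite(pred)]
  cellHm2 <- (ref@cellSize / 100)^2   # 1 hm^2 == 100 m x 100 m
  summary <- list(
    min = if (length(v)) min(v) else NA_real_,
    max = if (length(v)) max(v) else NA_real_,
    mean = if (length(v)) mean(v) else NA_real_,
    total_1e4_t = if (length(v)) sum(v) * cellHm2 / 1e4 else NA_real_,
    n_cells = length(v), cell_size_m = ref@cellSize)
  list(map = map, summary = summary)
}
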