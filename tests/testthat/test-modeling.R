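constRaster <- function(value, extent = tinyExtent, res = 1000) {
  nc <- ceiling((extent["xmax"] - extent["xmin"]) / res)
  nr <- ceiling((extent["ymax"] - extent["ymin"]) / res)
  rasterGrid(matrix(value, nr, nc), extent["xmin"], extent["ymax"], res)
}

test_that("feature extraction reads the containing raster cell", {
  plots <- data.frame(plot_id = c("a", "b"), x = c(500, 3100),
                      y = c(500, 4700), agb_t_hm2 = c(10, 20))
  fm <- extractFeatures(plots, list(m1 = constRaster(3.5)))
  expect_equal(fm$m1, c(3.5, 3.5))
  expect_equal(fm$agb_t_hm2, c(10, 20))
})

test_that("plots outside the extent are excluded with a report", {
  plots <- data.frame(plot_id = c("in", "out"), x = c(500, 99999),
                      y = c(500, 500), agb_t_hm2 = c(10, 20))
  expect_warning(fm <- extractFeatures(plots, list(m1 = constRaster(1))),
                 "excluded")
  expect_equal(fm$plot_id, "in")
  expect_equal(attr(fm, "exclusionReport")$excluded_plot_ids, "out")
  # all plots outside -> empty matrix, complete report
  allOut <- data.frame(plot_id = c("o1", "o2"), x = c(-1, -2) * 1e5,
                       y = 0, agb_t_hm2 = 1:2)
  expect_warning(fm0 <- extractFeatures(allOut, list(m1 = constRaster(1))))
  expect_equal(nrow(fm0), 0)
  expect_setequal(attr(fm0, "exclusionReport")$excluded_plot_ids,
                  c("o1", "o2"))
})

test_that("correlation screening ranks by |r| with significance marks", {
  set.seed(5)
  n <- 100
  y <- rnorm(n, 100, 30)
  fm <- data.frame(plot_id = seq_len(n),
                   same = y, anti = -y, noise = rnorm(n),
                   flat = rep(1, n), agb_t_hm2 = y)
  sc <- correlationScreen(fm, topK = 2)
  expect_equal(sc$variable[1:2], c("same", "anti"))
  expect_equal(sc$r[1], 1)
  expect_equal(sc$r[2], -1)
  expect_equal(sc$significance[1:2], c("**", "**"))
  expect_true(all(sc$selected[1:2]))
  # zero-variance feature is flagged and ranked last
  expect_equal(sc$variable[4], "flat")
  expect_false(sc$defined[4])
  expect_false(sc$selected[4])
})

test_that("screening recovers a known correlation of 0.6", {
  set.seed(11)
  n <- 200
  z <- rnorm(n)
  x <- 0.6 * z + sqrt(1 - 0.36) * rnorm(n)
  fm <- data.frame(plot_id = seq_len(n), x = x, agb_t_hm2 = z)
  sc <- correlationScreen(fm, topK = 1)
  expect_lt(abs(sc$r[1] - 0.6), 0.1)
})

test_that("cross-validation folds partition the plots exactly once", {
  set.seed(2)
  n <- 60
  fm <- data.frame(plot_id = seq_len(n), f1 = rnorm(n),
                   agb_t_hm2 = rnorm(n, 100, 20))
  cv <- fitAndCrossValidate(fm, "f1", modelConfig("rf", ntree = 50,
                                                  seed = 3), nFolds = 10)
  expect_equal(sort(unique(cv$folds)), 1:10)
  expect_equal(tabulate(cv$folds), rep(6, 10))
  expect_true(all(is.finite(cv$oof_predictions$predicted)))
  # identical seed -> identical folds and predictions
  cv2 <- fitAndCrossValidate(fm, "f1", modelConfig("rf", ntree = 50,
                                                   seed = 3), nFolds = 10)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$oof_predictions$predicted,
                   cv2$oof_predictions$predicted)
})

test_that("random forest recovers a noiseless functional response", {
  set.seed(7)
  n <- 200
  x1 <- runif(n, 0, 10)
  fm <- data.frame(plot_id = seq_len(n), x1 = x1, x2 = rnorm(n),
                   agb_t_hm2 = 3 * x1 + 5)
  cv <- fitAndCrossValidate(fm, c("x1", "x2"), modelConfig("rf", seed = 1))
  expect_gt(cv$pooled_metrics$r2, 0.9)
})

test_that("a permuted response yields no spurious skill", {
  set.seed(8)
  n <- 150
  x1 <- runif(n)
  fm <- data.frame(plot_id = seq_len(n), x1 = x1,
                   agb_t_hm2 = sample(2 * x1 + rnorm(n, 0, 0.1)))
  cv <- fitAndCrossValidate(fm, "x1", modelConfig("rf", seed = 2))
  expect_lte(cv$pooled_metrics$r2, 0.1)
})

test_that("all three estimators run under the study hyperparameters", {
  set.seed(9)
  n <- 80
  z <- runif(n, 0, 1)
  fm <- data.frame(plot_id = seq_len(n), f = z,
                   agb_t_hm2 = 100 + 50 * z + rnorm(n, 0, 5))
  for (alg in c("rf", "svm", "knn")) {
    cv <- fitAndCrossValidate(fm, "f", modelConfig(alg, seed = 4))
    expect_gt(cv$pooled_metrics$r2, 0.3)
  }
  expect_error(modelConfig("boost"))
  expect_error(modelConfig("rf", ntree = 0), "positive")
})

test_that("constant-feature rasters give a constant map with sane summary", {
  set.seed(10)
  n <- 50
  fm <- data.frame(plot_id = seq_len(n), f = runif(n),
                   agb_t_hm2 = rnorm(n, 100, 20))
  cv <- fitAndCrossValidate(fm, "f", modelConfig("rf", ntree = 50, seed = 1))
  out <- predictMap(cv, list(f = constRaster(0.5)))
  v <- gridValues(out$map)
  expect_equal(max(v) - min(v), 0)
  expect_equal(out$summary$min, out$summary$max)
  expect_equal(out$summary$n_cells, length(v))
  # total = mean density x mapped area (1000 m cells = 100 hm2 each)
  expect_equal(out$summary$total_1e4_t,
               out$summary$mean * out$summary$n_cells * 100 / 1e4)
})

test_that("averaging predictors stay within the training response range", {
  set.seed(12)
  n <- 60
  fm <- data.frame(plot_id = seq_len(n), f = runif(n),
                   agb_t_hm2 = runif(n, 50, 180))
  feat <- constRaster(0)
  vals <- matrix(seq(-5, 5, length.out = prod(dim(feat))), nrow(gridValues(feat)))
  ras <- rasterGrid(vals, 0, 6000, 1000)   # features far outside training
  for (alg in c("rf", "knn")) {
    cv <- fitAndCrossValidate(fm, "f", modelConfig(alg, ntree = 50, seed = 2))
    out <- predictMap(cv, list(f = ras))
    v <- gridValues(out$map)
    expect_gte(min(v), cv$train_range[1])
    expect_lte(max(v), cv$train_range[2])
    expect_lte(out$summary$min, out$summary$mean)
    expect_lte(out$summary$mean, out$summary$max)
  }
})

test_that("misaligned rasters and a mask are handled", {
  set.seed(13)
  n <- 40
  fm <- data.frame(plot_id = seq_len(n), f = runif(n), g = runif(n),
                   agb_t_hm2 = rnorm(n, 100, 10))
  cv <- fitAndCrossValidate(fm, c("f", "g"),
                            modelConfig("rf", ntree = 50, seed = 1))
  expect_error(predictMap(cv, list(f = constRaster(1),
                                   g = constRaster(1, res = 500))),
               "alignment error")
  mask <- constRaster(1)
  mv <- gridValues(mask); mv[1, ] <- 0
  mask <- rasterGrid(mv, 0, 6000, 1000)
  out <- predictMap(cv, list(f = constRaster(1), g = constRaster(2)),
                    mask = mask)
  expect_equal(out$summary$n_cells, prod(dim(mask)) - ncol(gridValues(mask)))
  expect_true(all(is.na(gridValues(out$map)[1, ])))
})
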