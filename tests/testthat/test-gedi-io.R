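## minimal table with controllable quality fields
qualityTable <- function(quality, degrade, sensitivity) {
  n <- length(quality)
  data.frame(shot_id = seq_len(n) - 1L, beam = "BEAM01", track = "T01",
             x = seq_len(n) * 60, y = 0, quality_flag = quality,
             degrade_flag = degrade, sensitivity = sensitivity)
}

test_that("the quality filter applies the three forest criteria", {
  t <- qualityTable(c(1, 1, 0, 1), c(0, 0, 0, 1), c(0.95, 0.89, 0.95, 0.95))
  kept <- filterFootprints(t)
  expect_equal(kept$shot_id, 0L)      # (1, 0, 0.95) is the only survivor
  rep <- attr(kept, "filterReport")
  expect_equal(rep$n_input, 4)
  expect_equal(rep$n_kept, 1)
  expect_equal(rep$removed_quality_flag, 1)
  expect_equal(rep$removed_degrade_flag, 1)
  expect_equal(rep$removed_sensitivity, 1)
})

test_that("an all-passing table is kept whole and order is preserved", {
  t <- qualityTable(rep(1, 20), rep(0, 20), rep(0.95, 20))
  kept <- filterFootprints(t)
  expect_equal(nrow(kept), 20)
  expect_equal(kept$shot_id, t$shot_id)
})

test_that("filtering is idempotent", {
  set.seed(1)
  t <- qualityTable(rbinom(200, 1, 0.9), rbinom(200, 1, 0.1),
                    runif(200, 0.8, 1))
  once <- filterFootprints(t)
  twice <- filterFootprints(once)
  attr(once, "filterReport") <- attr(twice, "filterReport") <- NULL
  expect_identical(once, twice)
})

test_that("a relaxed sensitivity threshold keeps low-sensitivity shots", {
  t <- qualityTable(1, 0, 0.85)
  expect_equal(nrow(filterFootprints(t)), 0)
  expect_equal(nrow(filterFootprints(t, filterCriteria(sensitivityMin = 0.8))),
               1)
  expect_error(filterCriteria(sensitivityMin = 1.2), "sensitivityMin")
})

test_that("interval thinning keeps every k-th shot within each beam", {
  t <- qualityTable(rep(1, 1000), rep(0, 1000), rep(0.95, 1000))
  expect_equal(nrow(thinFootprints(t, 10)), 100)
  expect_identical(thinFootprints(t, 1), t)          # identity
  t137 <- qualityTable(rep(1, 137), rep(0, 137), rep(0.95, 137))
  expect_equal(thinFootprints(t137, 100)$shot_id, c(0L, 100L))
  expect_error(thinFootprints(t, 0), "interval")
})

test_that("thinned size matches the per-beam counting formula", {
  set.seed(4)
  sizes <- c(37, 101, 250, 999)
  tabs <- lapply(seq_along(sizes), function(i) {
    qt <- qualityTable(rep(1, sizes[i]), rep(0, sizes[i]),
                       rep(0.95, sizes[i]))
    qt$beam <- sprintf("BEAM%02d", i)
    qt
  })
  t <- do.call(rbind, tabs)
  t <- t[sample(nrow(t)), ]   # order must not matter
  for (k in c(3, 10, 100)) {
    for (off in c(0, 2)) {
      expect_equal(nrow(thinFootprints(t, k, offset = off)),
                   sum(ceiling((sizes - off) / k)))
    }
  }
  # pooled mode thins the combined stream instead
  expect_equal(nrow(thinFootprints(t, 100, perBeam = FALSE)),
               ceiling(sum(sizes) / 100))
})

test_that("random-offset thinning is seeded and keeps the right count", {
  t <- qualityTable(rep(1, 500), rep(0, 500), rep(0.95, 500))
  a <- thinFootprints(t, 10, random = TRUE, seed = 3)
  b <- thinFootprints(t, 10, random = TRUE, seed = 3)
  expect_identical(a, b)
  expect_equal(nrow(a), 50)
})

test_that("footprint tables round-trip bit-exactly through CSV", {
  sc <- tinyScene(seed = 3)
  fp <- sc$footprints[1:50, ]
  path <- withr::local_tempfile(fileext = ".csv")
  writeFootprintsCSV(fp, path)
  back <- readFootprintsCSV(path)
  for (m in gediMetricNames()) expect_identical(back[[m]], fp[[m]])
  expect_identical(back$x, fp$x)
  expect_identical(back$shot_id, fp$shot_id)
})

test_that("GeoJSON export is a parseable FeatureCollection", {
  sc <- tinyScene(seed = 3)
  fp <- sc$footprints[1:5, ]
  path <- withr::local_tempfile(fileext = ".geojson")
  writeFootprintsGeoJSON(fp, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), 5)
  expect_equal(gj$features[[1]]$geometry$coordinates[[1]], fp$x[1])
  expect_equal(gj$features[[1]]$properties$pai, fp$pai[1])
})

test_that("schema violations are reported by name", {
  t <- qualityTable(1, 0, 0.95)
  expect_error(assertFootprintTable(t), "missing columns: cover")
  expect_error(filterFootprints(t[setdiff(names(t), "sensitivity")]),
               "quality fields")
})

test_that("L2B HDF5 beam groups round-trip through the h5py reader", {
  h5 <- withr::local_tempfile(fileext = ".h5")
  py <- withr::local_tempfile(fileext = ".py")
  metrics <- gediMetricNames()
  writeLines(c(
    "import h5py, numpy as np, sys",
    sprintf("f = h5py.File('%s', 'w')", h5),
    "rng = np.random.default_rng(0)",
    "for beam in ['BEAM0000', 'BEAM0001']:",
    "    g = f.create_group(beam)",
    "    g['shot_number'] = np.arange(5)",
    "    g['geolocation/lon_lowestmode'] = rng.uniform(0, 1000, 5)",
    "    g['geolocation/lat_lowestmode'] = rng.uniform(0, 1000, 5)",
    paste0("    for m in ", sprintf("[%s]", paste(sprintf("'%s'", metrics),
                                                  collapse = ",")), ":"),
    "        g[m] = rng.normal(size=5)",
    "    g['quality_flag'] = np.ones(5, dtype=int)",
    "    g['degrade_flag'] = np.zeros(5, dtype=int)",
    "f.close()"), py)
  res <- system2(Sys.which("python"), py, stdout = TRUE, stderr = TRUE)
  expect_null(attr(res, "status"))
  tab <- readL2B(h5, c("BEAM0000", "BEAM0001"))
  expect_equal(nrow(tab), 10)
  expect_setequal(unique(tab$beam), c("BEAM0000", "BEAM0001"))
  expect_true(all(metrics %in% names(tab)))
  # requesting an absent metric names the missing path
  expect_error(readL2B(h5, "BEAM0000", metrics = c("pai", "nonexistent")),
               "missing dataset.*nonexistent")
})
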