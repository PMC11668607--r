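test_that("a single measured point is returned everywhere", {
  pts <- data.frame(shot_id = 1, x = 123, y = 456, v = 7.3)
  expect_equal(idwPredict(c(0, 1000, -50), c(0, 2000, 300), pts, "v"),
               rep(7.3, 3))
})

test_that("IDW is an exact interpolator at measured points", {
  pts <- randomFootprints(50, seed = 2)
  got <- idwPredict(pts$x, pts$y, pts, "v")
  expect_identical(got, pts$v)
})

test_that("the three-point worked example matches the weight formula", {
  pts <- data.frame(shot_id = 1:3, x = c(1, 2, 4), y = 0, v = c(0, 6, 12))
  # weights 1, 1/4, 1/16 at p = 2: (6/4 + 12/16) / (1 + 1/4 + 1/16) = 12/7
  expect_equal(idwPredict(0, 0, pts, "v", idwParams(nNeighbors = 0)),
               12 / 7, tolerance = 1e-12)
})

test_that("predictions agree with the brute-force oracle to 1e-10", {
  pts <- randomFootprints(400, seed = 5)
  set.seed(6)
  qx <- runif(300, 0, 6000)
  qy <- runif(300, 0, 6000)
  for (p in list(idwParams(power = 2, nNeighbors = 12),
                 idwParams(power = 1, nNeighbors = 0),
                 idwParams(power = 2, nNeighbors = 5))) {
    got <- idwPredict(qx, qy, pts, "v", p)
    want <- idwOracle(qx, qy, pts, "v", power = p$power,
                      nNeighbors = p$nNeighbors)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("rasterisation equals the brute-force oracle on a 10x10 grid", {
  pts <- randomFootprints(120, seed = 9)
  g <- idwRasterize(pts, "v", tinyExtent, resolutionM = 600)
  cc <- cellCenters(g)
  want <- idwOracle(cc$x, cc$y, pts, "v")
  expect_equal(as.numeric(t(gridValues(g))), want, tolerance = 1e-10)
})

test_that("predictions respect the convex bound of measured values", {
  pts <- randomFootprints(200, seed = 3)
  set.seed(4)
  qx <- runif(1000, -500, 6500)   # includes extrapolation outside the hull
  qy <- runif(1000, -500, 6500)
  got <- idwPredict(qx, qy, pts, "v")
  expect_true(all(got >= min(pts$v) - 1e-12))
  expect_true(all(got <= max(pts$v) + 1e-12))
})

test_that("constant measurements give a constant raster", {
  pts <- randomFootprints(30, seed = 1, valueFun = function(x, y) 0)
  pts$v <- 4.2
  g <- idwRasterize(pts, "v", tinyExtent, resolutionM = 1000)
  expect_equal(gridValues(g), matrix(4.2, 6, 6), tolerance = 1e-12)
})

test_that("neighbour-limited and all-point predictions agree when n <= N", {
  pts <- randomFootprints(10, seed = 7)
  set.seed(8)
  qx <- runif(50, 0, 6000); qy <- runif(50, 0, 6000)
  a <- idwPredict(qx, qy, pts, "v", idwParams(nNeighbors = 12))
  b <- idwPredict(qx, qy, pts, "v", idwParams(nNeighbors = 0))
  expect_identical(a, b)
})

test_that("search radius produces nodata and empty input errors", {
  pts <- data.frame(shot_id = 1, x = 0, y = 0, v = 1)
  p <- idwParams(maxSearchRadiusM = 100)
  got <- idwPredict(c(10, 5000), c(0, 0), pts, "v", p)
  expect_equal(got[1], 1)
  expect_true(is.na(got[2]))
  expect_error(idwPredict(0, 0, pts[0, ], "v"), "empty measured table")
  expect_error(idwParams(power = 0), "power")
})

test_that("equidistant neighbour ties break on the lower shot id", {
  # four corners at identical distance; N = 2 must take shot ids 1 and 2
  pts <- data.frame(shot_id = c(3, 1, 4, 2),
                    x = c(1, -1, -1, 1), y = c(1, 1, -1, -1),
                    v = c(100, 1, 100, 3))
  got <- idwPredict(0, 0, pts, "v", idwParams(nNeighbors = 2))
  expect_equal(got, 2)   # mean of values 1 and 3
})
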