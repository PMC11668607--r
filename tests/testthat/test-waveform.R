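test_that("smoothing leaves a constant waveform unchanged", {
  w <- waveform(rep(5, 100))
  expect_equal(intensities(gaussianSmooth(w, 6.5)), rep(5, 100),
               tolerance = 1e-12)
})

test_that("a smoothed interior impulse is a unit-sum Gaussian kernel", {
  v <- numeric(201); v[101] <- 1
  sm <- intensities(gaussianSmooth(waveform(v), 6.5))
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_equal(which.max(sm), 101)
})

test_that("smoothing matches a direct-convolution oracle", {
  set.seed(8)
  v <- rnorm(300, 100, 1)
  v[100:140] <- v[100:140] + c(1:21, 20:1) * 2   # triangular peak at 120
  v[200:215] <- v[200:215] + c(1:8, 8:1) * 3     # triangular peak at ~207
  for (widthNs in c(3, 6.5)) {
    sm <- intensities(gaussianSmooth(waveform(v, binWidthNs = 1), widthNs))
    expect_equal(sm, convOracle(v, widthNs), tolerance = 1e-10)
  }
  # peaks are lowered but stay in place (within one bin)
  sm <- intensities(gaussianSmooth(waveform(v), 6.5))
  expect_lt(max(sm[90:150]), max(v[90:150]))
  expect_lt(abs(which.max(sm[90:150]) - which.max(v[90:150])), 2)
})

test_that("smoothing is shift-equivariant away from the boundaries", {
  v <- numeric(400); v[150:170] <- 30
  s1 <- intensities(gaussianSmooth(waveform(v), 6.5))
  s2 <- intensities(gaussianSmooth(waveform(c(numeric(25), v[1:375])), 6.5))
  expect_equal(s2[101:300], s1[76:275], tolerance = 1e-10)
})

test_that("the fwhm interpretation narrows the kernel", {
  v <- numeric(201); v[101] <- 1
  sigma <- intensities(gaussianSmooth(waveform(v), 6.5, "sigma"))
  fwhm <- intensities(gaussianSmooth(waveform(v), 6.5, "fwhm"))
  expect_gt(max(fwhm), max(sigma))
})

test_that("the noise threshold is mean + c * std, exactly", {
  expect_identical(computeThreshold(waveform(0, noiseMean = 10,
                                             noiseStd = 2, constantC = 4)),
                   18)
  expect_identical(computeThreshold(waveform(0, noiseMean = 7.5,
                                             noiseStd = 3, constantC = 0)),
                   7.5)
})

test_that("a c >= 3 threshold is exceeded by under 1% of pure noise bins", {
  w <- simulateWaveform(20000, noiseMean = 50, noiseStd = 2, seed = 6)
  v <- intensities(w)
  thr <- mean(v) + 3 * sd(v)   # statistics estimated from the waveform
  expect_lt(mean(v > thr), 0.01)
})

test_that("pure noise below threshold yields empty bounds", {
  w <- simulateWaveform(500, noiseMean = 100, noiseStd = 1,
                        constantC = 8, seed = 2)
  b <- detectSignalBounds(gaussianSmooth(w))
  expect_true(is.na(b$searchstart) && is.na(b$searchend))
  expect_true(is.na(b$toploc) && is.na(b$botloc))
})

test_that("an isolated super-threshold bin has no toploc/botloc", {
  v <- numeric(11); v[6] <- 10
  b <- detectSignalBounds(waveform(v, noiseMean = 0, noiseStd = 1,
                                   constantC = 4))
  expect_equal(b$searchstart, 6)
  expect_equal(b$searchend, 6)
  expect_true(is.na(b$toploc) && is.na(b$botloc))
})

test_that("a strong bump at bins 200-260 is bounded within [195, 265]", {
  w <- simulateWaveform(500, noiseMean = 100, noiseStd = 1,
                        signalSegments = data.frame(start = 200, end = 260,
                                                    amplitude = 50),
                        binWidthNs = 2, constantC = 4.5, seed = 3)
  expect_equal(unname(signalTruth(w)[1, ]), c(200L, 260L))
  b <- detectSignalBounds(gaussianSmooth(w, 6.5))
  expect_gte(b$toploc, 195)
  expect_lte(b$botloc, 265)
  # detected pair-extent covers the injected core
  expect_lte(b$toploc, 201)
  expect_gte(b$botloc, 259)
})

test_that("raising c never widens the search range", {
  w <- gaussianSmooth(simulateWaveform(600, noiseMean = 100, noiseStd = 2,
                                       signalSegments = data.frame(
                                         start = 250, end = 350,
                                         amplitude = 30), seed = 9))
  prev <- NULL
  for (cc in c(2, 3, 4.5, 6, 8)) {
    b <- detectSignalBounds(w, computeThreshold(w, cc))
    if (!is.null(prev) && !is.na(b$searchstart)) {
      expect_gte(b$searchstart, prev$searchstart)
      expect_lte(b$searchend, prev$searchend)
    }
    if (!is.na(b$searchstart)) prev <- b
  }
})

test_that("overlapping signal segments are merged with a warning", {
  expect_warning(
    w <- simulateWaveform(300, signalSegments = data.frame(
      start = c(50, 80), end = c(100, 140), amplitude = 20), seed = 1),
    "merged")
  expect_equal(unname(signalTruth(w)[1, ]), c(50L, 140L))
})

test_that("seeded waveform simulation is reproducible", {
  a <- simulateWaveform(256, seed = 42)
  b <- simulateWaveform(256, seed = 42)
  expect_identical(intensities(a), intensities(b))
})
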