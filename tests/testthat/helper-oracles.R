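## Independent brute-force oracles used to cross-check the package's
## computational paths.  These deliberately use naive loops and a separate
## code path from the implementation.

## plain R inverse-distance weighting, one query at a time
idwOracle <- function(qx, qy, measured, variable, power = 2,
                      nNeighbors = 12, zeroTol = 1e-9) {
  vapply(seq_along(qx), function(i) {
    d2 <- (measured$x - qx[i])^2 + (measured$y - qy[i])^2
    if (any(d2 < zeroTol^2)) {
      return(measured[[variable]][which(d2 < zeroTol^2)[1]])
    }
    key <- if ("shot_id" %in% names(measured)) measured$shot_id else
      seq_len(nrow(measured))
    ord <- order(d2, key)
    if (nNeighbors > 0 && nNeighbors < length(ord)) {
      ord <- ord[seq_len(nNeighbors)]
    }
    w <- d2[ord]^(-power / 2)
    sum(w * measured[[variable]][ord]) / sum(w)
  }, numeric(1))
}

## direct-sum Gaussian convolution with reflective padding
convOracle <- function(v, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- length(v)
  reflect <- function(i) {
    # reflect indices into 1..n without repeating the edge sample
    while (any(i < 1L | i > n)) {
      i[i < 1L] <- 2L - i[i < 1L]
      i[i > n] <- 2L * n - i[i > n]
    }
    i
  }
  sapply(seq_len(n), function(j) sum(k * v[reflect(j + (-r:r))]))
}

## empirical semivariance of a grid at a lag of `lag` columns
semivarOracle <- function(m, lag) {
  d <- m[, seq_len(ncol(m) - lag)] - m[, seq_len(ncol(m) - lag) + lag]
  mean(d^2) / 2
}

## a small synthetic scene, cheap enough for unit tests
tinyScene <- function(seed = 1L, ...) {
  simulateScene(
    seed = seed,
    extent = c(xmin = 0, xmax = 6000, ymin = 0, ymax = 6000),
    resolutionM = 120,
    overpassAzimuths = seq(0, 157.5, length.out = 8),
    nPlots = 40L, ...)
}

tinyExtent <- c(xmin = 0, xmax = 6000, ymin = 0, ymax = 6000)

## a minimal single-metric field set over a small extent
tinyField <- function(seed = 1L, sill = 0.25, mean = 2.5, rangeM = 1000,
                      nugget = 0, extent = c(xmin = 0, xmax = 3000,
                                             ymin = 0, ymax = 3000),
                      resolutionM = 100, metric = "pai") {
  sp <- fieldSpec(extent, stats::setNames(mean, metric),
                  stats::setNames(sill, metric),
                  rangeM = rangeM, nugget = nugget, seed = seed)
  generateField(sp, resolutionM)
}

## random footprint table (non-track, uniform) for IDW tests
randomFootprints <- function(n, seed = 1L, extent = tinyExtent,
                             valueFun = function(x, y) x / 1000 + y / 2000) {
  set.seed(seed)
  x <- runif(n, extent["xmin"], extent["xmax"])
  y <- runif(n, extent["ymin"], extent["ymax"])
  data.frame(shot_id = seq_len(n), beam = "BEAM01", track = "T01",
             x = x, y = y, v = valueFun(x, y) + rnorm(n, 0, 0.1))
}
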