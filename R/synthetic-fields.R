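#' Specification of spatially autocorrelated metric fields
#'
#' Describes one Gaussian random field per footprint metric over a planar
#' rectangular extent, with an exponential covariance model
#' \eqn{C(h) = s\,(1-\eta)\exp(-h/r) + s\,\eta\,\delta(h)} where `s` is the
#' sill (total variance), `r` the correlation range and `eta` the nugget
#' fraction of micro-scale (white) variance.
#'
#' @param extent named numeric `c(xmin, xmax, ymin, ymax)` in metres.
#' @param means named numeric vector: mean value per metric.
#' @param sills named numeric vector (> 0, or 0 for a constant field), same
#'   names as `means`.
#' Metrics are not independent: canopy cover, PAI, FHD, gap probability
#' and the waveform energy integrals are all expressions of one canopy
#' density gradient.  This is modelled by a shared latent field: metric m
#' is built as \eqn{a_m L + \sqrt{1-a_m^2}\, e_m} from the latent field L
#' and an independent component \eqn{e_m}, so `latentShare` \eqn{a_m} in
#' \[-1, 1\] sets the cross-correlation structure (metrics m, n correlate
#' as \eqn{a_m a_n} before the nugget).
#'
#' @param rangeM spatial correlation range in metres (> 0).
#' @param nugget micro-scale variance fraction in \[0, 1\].
#' @param latentShare named numeric vector of latent loadings in
#'   \[-1, 1\] per metric; metrics not named load 0 (independent).
#' @param seed integer seed; the field set is a pure function of the spec.
#' @return object of class `fieldSpec`.
#' @seealso [generateField()]
#' @export
fieldSpec <- function(extent, means, sills, rangeM = 2000, nugget = 0.05,
                      latentShare = NULL, seed = 1L) {
  extent <- checkExtent(extent)
  if (is.null(names(means)) || is.null(names(sills)) ||
      !setequal(names(means), names(sills))) {
    stop("means and sills must be named vectors over the same metrics")
  }
  sills <- sills[names(means)]
  if (any(!is.finite(sills)) || any(sills < 0)) {
    stop("sills must be finite and >= 0")
  }
  if (!is.finite(rangeM) || rangeM <= 0) stop("rangeM must be > 0")
  if (!is.finite(nugget) || nugget < 0 || nugget > 1) {
    stop("nugget must lie in [0, 1]")
  }
  share <- stats::setNames(rep(0, length(means)), names(means))
  if (!is.null(latentShare)) {
    bad <- setdiff(names(latentShare), names(means))
    if (length(bad)) stop("latentShare names not in metrics: ",
                          paste(bad, collapse = ", "))
    if (any(abs(latentShare) > 1)) stop("latentShare must lie in [-1, 1]")
    share[names(latentShare)] <- latentShare
  }
  structure(list(extent = extent, means = means, sills = sills,
                 rangeM = rangeM, nugget = nugget, latentShare = share,
                 seed = as.integer(seed)),
            class = "fieldSpec")
}

checkExtent <- function(extent) {
  if (length(extent) != 4L) stop("extent must be c(xmin, xmax, ymin, ymax)")
  if (is.null(names(extent))) names(extent) <- c("xmin", "xmax",
                                                 "ymin", "ymax")
  extent <- extent[c("xmin", "xmax", "ymin", "ymax")]
  if (any(!is.finite(extent)) || extent["xmax"] <= extent["xmin"] ||
      extent["ymax"] <= extent["ymin"]) {
    stop("invalid specification: degenerate extent")
  }
  extent
}

#' Generate spatially autocorrelated metric fields
#'
#' Simulates one Gaussian random field per metric on a regular grid by
#' circulant embedding: the exponential covariance is laid out on a torus
#' twice the grid size, its eigenvalues are obtained by FFT (tiny negative
#' eigenvalues from the embedding are clamped to zero), and a field with
#' exactly that covariance is drawn in the spectral domain.  Nugget
#' variance is added as independent per-cell noise.  A sill of zero yields
#' a constant field equal to the mean.
#'
#' All metrics share the spatial correlation structure (same range and
#' nugget fraction); cross-correlation between metrics follows the spec's
#' latent loadings.  Proportion metrics (`sensitivity`, `cover`,
#' `pgap_thea`) are clamped to \[0, 1\] after simulation.
#'
#' @param spec a [fieldSpec()].
#' @param resolutionM grid cell size in metres (> 0).
#' @return named list of [RasterGrid-class] objects, one per metric.
#' @examples
#' sp <- fieldSpec(c(xmin = 0, xmax = 3000, ymin = 0, ymax = 3000),
#'                 means = c(pai = 2.5), sills = c(pai = 0.25),
#'                 rangeM = 500, seed = 7)
#' f <- generateField(sp, 100)
#' f$pai
#' @export
generateField <- function(spec, resolutionM) {
  stopifnot(inherits(spec, "fieldSpec"))
  if (!is.finite(resolutionM) || resolutionM <= 0) {
    stop("invalid specification: resolutionM must be > 0")
  }
  ex <- spec$extent
  nc <- max(1L, ceiling((ex["xmax"] - ex["xmin"]) / resolutionM))
  nr <- max(1L, ceiling((ex["ymax"] - ex["ymin"]) / resolutionM))
  set.seed(spec$seed)
  lam <- unitCovEigenvalues(nr, nc, resolutionM, spec$rangeM)
  latent <- drawCirculantField(lam, nr, nc)
  out <- vector("list", length(spec$means))
  names(out) <- names(spec$means)
  for (m in names(spec$means)) {
    s <- spec$sills[[m]]
    if (s == 0) {
      v <- matrix(spec$means[[m]], nr, nc)
    } else {
      a <- spec$latentShare[[m]]
      z <- a * latent +
        sqrt(1 - a^2) * drawCirculantField(lam, nr, nc)
      z <- z * sqrt(s * (1 - spec$nugget)) +
        matrix(stats::rnorm(nr * nc, 0, sqrt(s * spec$nugget)), nr, nc)
      v <- spec$means[[m]] + z
      if (m == "sensitivity") v <- pmin(pmax(v, 0), 1)
      if (m %in% c("cover", "pgap_thea")) v <- pmin(pmax(v, 0), 1)
    }
    out[[m]] <- rasterGrid(v, ex["xmin"], ex["ymax"], resolutionM)
  }
  out
}

## eigenvalues of the circulant embedding of a unit-sill exponential
## covariance (nugget excluded) on a (2 nr) x (2 nc) torus
unitCovEigenvalues <- function(nr, nc, h, rangeM) {
  m1 <- 2L * nr
  m2 <- 2L * nc
  di <- pmin(0:(m1 - 1L), m1 - 0:(m1 - 1L)) * h
  dj <- pmin(0:(m2 - 1L), m2 - 0:(m2 - 1L)) * h
  D <- sqrt(outer(di^2, dj^2, "+"))
  lam <- Re(stats::fft(exp(-D / rangeM)))
  lam[lam < 0] <- 0   # embedding may be marginally non-PSD
  lam
}

## one unit-variance draw given precomputed embedding eigenvalues
drawCirculantField <- function(lam, nr, nc) {
  m1 <- nrow(lam)
  m2 <- ncol(lam)
  eps <- matrix(stats::rnorm(m1 * m2), m1, m2) +
    1i * matrix(stats::rnorm(m1 * m2), m1, m2)
  x <- Re(stats::fft(sqrt(lam) * eps)) / sqrt(m1 * m2)
  x[seq_len(nr), seq_len(nc), drop = FALSE]
}
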