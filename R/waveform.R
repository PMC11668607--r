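#' Gaussian smoothing of a waveform
#'
#' Convolves the intensities with a unit-area discrete Gaussian kernel.
#' The smoothing width is given in nanoseconds and converted to bins via
#' the bin width; by default it is interpreted as the Gaussian sigma (the
#' common reading of a "filter width"), with `interpretation = "fwhm"`
#' available.  Boundaries are handled by reflective padding, which leaves
#' a constant waveform exactly unchanged and conserves the energy of any
#' interior-supported signal.
#'
#' @param w a [Waveform-class].
#' @param widthNs smoothing width in nanoseconds (> 0); default 6.5.
#' @param interpretation `"sigma"` (default) or `"fwhm"`.
#' @return A smoothed [Waveform-class] (same length, truth carried over).
#' @export
gaussianSmooth <- function(w, widthNs = 6.5,
                           interpretation = c("sigma", "fwhm")) {
  stopifnot(is(w, "Waveform"))
  if (widthNs <= 0) stop("widthNs must be > 0")
  interpretation <- match.arg(interpretation)
  sigma <- widthNs / w@binWidthNs
  if (interpretation == "fwhm") sigma <- sigma / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)                       # unit area after truncation
  v <- w@intensities
  n <- length(v)
  pad <- pmin(r, n - 1L)
  ## reflective padding (without repeating the edge sample)
  left <- if (pad > 0) v[(pad + 1L):2L] else numeric()
  right <- if (pad > 0) v[(n - 1L):(n - pad)] else numeric()
  ext <- c(rep(v[1L], r - pad), left, v, right, rep(v[n], r - pad))
  sm <- as.numeric(stats::filter(ext, k, sides = 2))
  sm <- sm[(r + 1L):(r + n)]
  out <- w
  out@intensities <- sm
  out
}

#' Background-noise threshold of a waveform
#'
#' The signal-detection threshold is the noise mean plus `c` times the
#' noise standard deviation, with `c` the constant stored on the waveform
#' (overridable).
#'
#' @param w a [Waveform-class] with noise statistics set.
#' @param c threshold constant; defaults to the waveform's `constantC`.
#' @return numeric threshold: `noiseMean + c * noiseStd`, exactly.
#' @examples
#' computeThreshold(waveform(0, noiseMean = 10, noiseStd = 2, constantC = 4))
#' @export
computeThreshold <- function(w, c = NULL) {
  stopifnot(is(w, "Waveform"))
  if (is.null(c)) c <- w@constantC
  w@noiseMean + c * w@noiseStd
}

#' Detect the signal extent of a (smoothed) waveform
#'
#' `searchstart` and `searchend` are the first and last bins whose
#' intensity exceeds the threshold.  Within that search range, `toploc`
#' and `botloc` are the outermost positions at which two *adjacent* bins
#' both exceed the threshold — the highest and lowest reliably detectable
#' echoes.  When no bin exceeds the threshold all four indices are `NA`
#' (an empty-bounds result, not an error); an isolated single
#' super-threshold bin yields `searchstart == searchend` with empty
#' toploc/botloc.
#'
#' @param w a [Waveform-class], normally smoothed first with
#'   [gaussianSmooth()].
#' @param threshold detection threshold; defaults to [computeThreshold()].
#' @return list of class `signalBounds` with integer elements
#'   `searchstart`, `searchend`, `toploc`, `botloc` (`NA` when absent).
#' @export
detectSignalBounds <- function(w, threshold = computeThreshold(w)) {
  stopifnot(is(w, "Waveform"))
  v <- w@intensities
  above <- which(v > threshold)
  if (!length(above)) {
    return(structure(list(searchstart = NA_integer_,
                          searchend = NA_integer_,
                          toploc = NA_integer_, botloc = NA_integer_),
                     class = "signalBounds"))
  }
  ss <- above[1L]
  se <- above[length(above)]
  top <- NA_integer_
  bot <- NA_integer_
  if (se > ss) {
    idx <- ss:(se - 1L)
    pair <- v[idx] > threshold & v[idx + 1L] > threshold
    if (any(pair)) {
      top <- idx[which(pair)[1L]]
      bot <- idx[max(which(pair))] + 1L
    }
  }
  structure(list(searchstart = ss, searchend = se,
                 toploc = top, botloc = bot),
            class = "signalBounds")
}

#' @export
print.signalBounds <- function(x, ...) {
  if (is.na(x$searchstart)) {
    cat("signalBounds: empty (no bin above threshold)\n")
  } else {
    cat(sprintf("signalBounds: search [%d, %d], toploc %s, botloc %s\n",
                x$searchstart, x$searchend,
                ifelse(is.na(x$toploc), "-", x$toploc),
                ifelse(is.na(x$botloc), "-", x$botloc)))
  }
  invisible(x)
}

#' Write a signal-bounds report as JSON
#' @param bounds a `signalBounds` result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeBoundsReport <- function(bounds, path) {
  jsonlite::write_json(lapply(unclass(bounds), function(v)
    if (is.na(v)) NULL else v), path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
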