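#' Simulate a LiDAR return waveform
#'
#' Builds a waveform as a Gaussian noise floor plus rectangular signal
#' segments of given amplitude, recording the injected segments as ground
#' truth for bounds-detection tests.  Overlapping or abutting segments are
#' merged with a warning.
#'
#' @param nBins number of time bins (> 0).
#' @param noiseMean,noiseStd noise floor mean and SD (SD >= 0).
#' @param signalSegments `NULL`, or a matrix/data.frame with columns
#'   `start`, `end`, `amplitude` (bin indices, 1-based, inclusive).
#' @param binWidthNs bin width in nanoseconds.
#' @param constantC threshold constant stored on the waveform.
#' @param seed integer seed.
#' @return A [Waveform-class]; the injected extent is in `signalTruth()`.
#' @export
simulateWaveform <- function(nBins, noiseMean = 100, noiseStd = 1,
                             signalSegments = NULL, binWidthNs = 1,
                             constantC = 4.5, seed = 1L) {
  if (nBins <= 0) stop("nBins must be > 0")
  if (noiseStd < 0) stop("noiseStd must be >= 0")
  set.seed(seed)
  v <- stats::rnorm(nBins, noiseMean, noiseStd)
  truth <- matrix(integer(), 0L, 2L, dimnames = list(NULL, c("start", "end")))
  if (!is.null(signalSegments) && NROW(signalSegments) > 0) {
    seg <- as.data.frame(signalSegments)
    stopifnot(all(c("start", "end", "amplitude") %in% names(seg)))
    seg <- seg[order(seg$start), , drop = FALSE]
    if (any(seg$start < 1 | seg$end > nBins | seg$start > seg$end)) {
      stop("signal segments must satisfy 1 <= start <= end <= nBins")
    }
    for (i in seq_len(nrow(seg))) {
      v[seg$start[i]:seg$end[i]] <- v[seg$start[i]:seg$end[i]] +
        seg$amplitude[i]
    }
    ## merge overlapping/abutting segments for the recorded truth
    m <- seg[1, c("start", "end")]
    if (nrow(seg) > 1) {
      merged <- FALSE
      for (i in 2:nrow(seg)) {
        last <- nrow(m)
        if (seg$start[i] <= m$end[last] + 1L) {
          m$end[last] <- max(m$end[last], seg$end[i])
          merged <- TRUE
        } else {
          m <- rbind(m, seg[i, c("start", "end")])
        }
      }
      if (merged) warning("overlapping signal segments merged")
    }
    truth <- as.matrix(m)
    storage.mode(truth) <- "integer"
    colnames(truth) <- c("start", "end")
  }
  new("Waveform", intensities = v, binWidthNs = binWidthNs,
      noiseMean = noiseMean, noiseStd = noiseStd, constantC = constantC,
      signalTruth = truth)
}

#' Construct a Waveform from raw intensities
#' @param intensities numeric vector of per-bin intensities.
#' @param binWidthNs bin width (ns).
#' @param noiseMean,noiseStd background-noise statistics.
#' @param constantC threshold constant c.
#' @return A [Waveform-class].
#' @export
waveform <- function(intensities, binWidthNs = 1, noiseMean = 0,
                     noiseStd = 0, constantC = 4.5) {
  new("Waveform", intensities = as.numeric(intensities),
      binWidthNs = binWidthNs, noiseMean = noiseMean, noiseStd = noiseStd,
      constantC = constantC,
      signalTruth = matrix(integer(), 0L, 2L,
                           dimnames = list(NULL, c("start", "end"))))
}

#' @export
setMethod("show", "Waveform", function(object) {
  cat(sprintf("Waveform: %d bins x %g ns; noise %g +/- %g, c = %g\n",
              length(object@intensities), object@binWidthNs,
              object@noiseMean, object@noiseStd, object@constantC))
  if (nrow(object@signalTruth)) {
    cat("  injected signal bins:",
        paste(sprintf("[%d, %d]", object@signalTruth[, 1],
                      object@signalTruth[, 2]), collapse = ", "), "\n")
  }
  invisible(object)
})

#' Per-bin intensities of a Waveform
#' @param w a `Waveform`.
#' @return numeric vector.
#' @export
intensities <- function(w) {
  stopifnot(is(w, "Waveform"))
  w@intensities
}

#' Injected signal extent of a simulated Waveform
#' @param w a `Waveform`.
#' @return integer matrix with columns `start`, `end` (0 rows if none).
#' @export
signalTruth <- function(w) {
  stopifnot(is(w, "Waveform"))
  w@signalTruth
}
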