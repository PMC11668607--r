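#' @import methods
NULL

#' RasterGrid: a regular axis-aligned grid of values
#'
#' Minimal single-band raster container used for synthetic metric fields,
#' IDW-interpolated surfaces and biomass maps.  The grid is row-major with
#' its origin at the *upper-left* corner: row 1 is the northernmost row and
#' cell centres sit half a cell inside the origin.  Missing cells are `NA`
#' internally and tagged with a nodata value on write.
#'
#' @slot originX x coordinate (m) of the upper-left corner of cell (1, 1).
#' @slot originY y coordinate (m) of the upper-left corner of cell (1, 1).
#' @slot cellSize cell edge length in metres (> 0).
#' @slot values numeric matrix, `nrow` rows (top to bottom) by `ncol`
#'   columns (west to east); `NA` marks nodata.
#'
#' @seealso [rasterGrid()], [writeAsciiGrid()], [valueAtXY()]
#' @export
setClass("RasterGrid",
  representation(
    originX = "numeric",
    originY = "numeric",
    cellSize = "numeric",
    values = "matrix"
  )
)

setValidity("RasterGrid", function(object) {
  msg <- character()
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0) {
    msg <- c(msg, "cellSize must be a single positive finite number")
  }
  if (length(object@originX) != 1L || !is.finite(object@originX)) {
    msg <- c(msg, "originX must be a single finite number")
  }
  if (length(object@originY) != 1L || !is.finite(object@originY)) {
    msg <- c(msg, "originY must be a single finite number")
  }
  if (!is.numeric(object@values)) {
    msg <- c(msg, "values must be a numeric matrix")
  }
  if (length(msg)) msg else TRUE
})

#' Waveform: a discretised LiDAR return waveform
#'
#' Holds received intensities per time bin together with the noise
#' statistics and the threshold constant used for signal-extent detection
#' (threshold = noise mean + c * noise std).
#'
#' @slot intensities numeric vector of per-bin intensities.
#' @slot binWidthNs time-bin width in nanoseconds (> 0).
#' @slot noiseMean mean of the background noise level.
#' @slot noiseStd standard deviation of the background noise (>= 0).
#' @slot constantC threshold constant c.
#' @slot signalTruth integer matrix with columns `start`, `end`: the bins
#'   where signal was injected by the simulator (empty for real data).
#'
#' @seealso [waveform()], [gaussianSmooth()], [detectSignalBounds()]
#' @export
setClass("Waveform",
  representation(
    intensities = "numeric",
    binWidthNs = "numeric",
    noiseMean = "numeric",
    noiseStd = "numeric",
    constantC = "numeric",
    signalTruth = "matrix"
  )
)

setValidity("Waveform", function(object) {
  msg <- character()
  if (!all(is.finite(object@intensities))) {
    msg <- c(msg, "intensities must all be finite")
  }
  if (length(object@binWidthNs) != 1L || object@binWidthNs <= 0) {
    msg <- c(msg, "binWidthNs must be a single positive number")
  }
  if (length(object@noiseStd) != 1L || object@noiseStd < 0) {
    msg <- c(msg, "noiseStd must be non-negative")
  }
  if (ncol(object@signalTruth) != 2L) {
    msg <- c(msg, "signalTruth must have two columns (start, end)")
  }
  if (length(msg)) msg else TRUE
})
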