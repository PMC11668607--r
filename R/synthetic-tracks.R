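#' Specification of the orbital sampling geometry
#'
#' Captures the acquisition geometry of a GEDI-like spaceborne LiDAR:
#' ~25 m footprints every 60 m along track, eight parallel beams 600 m
#' apart spanning a 4200 m swath, and several crossing overpasses whose
#' overlap produces the characteristic footprint lattice.
#'
#' Each overpass lays one beam family along its azimuth; the swath centre
#' line of each overpass is given a seeded random perpendicular offset
#' across the extent so that repeated overpasses tile the scene rather
#' than stacking on one line.
#'
#' @param alongTrackSpacingM shot spacing along each beam line (m).
#' @param crossTrackSpacingM spacing between adjacent beams (m).
#' @param swathWidthM total swath width (m); beams must fit inside it.
#' @param nBeams number of beams per overpass.
#' @param footprintDiameterM nominal footprint diameter (m), metadata only.
#' @param overpassAzimuths numeric vector of track azimuths in degrees
#'   (0 = north, clockwise); one overpass per element.
#' @param seed integer seed controlling the swath offsets.
#' @return object of class `orbitSpec`.
#' @export
orbitSpec <- function(alongTrackSpacingM = 60, crossTrackSpacingM = 600,
                      swathWidthM = 4200, nBeams = 8L,
                      footprintDiameterM = 25,
                      overpassAzimuths = c(15, 105), seed = 1L) {
  if (alongTrackSpacingM <= 0 || crossTrackSpacingM <= 0 ||
      swathWidthM <= 0) {
    stop("all spacings must be > 0")
  }
  if (nBeams < 1L) stop("nBeams must be >= 1")
  if ((nBeams - 1L) * crossTrackSpacingM > swathWidthM) {
    stop("beams do not fit in the swath: (nBeams-1)*crossTrackSpacingM > swathWidthM")
  }
  structure(list(alongTrackSpacingM = alongTrackSpacingM,
                 crossTrackSpacingM = crossTrackSpacingM,
                 swathWidthM = swathWidthM, nBeams = as.integer(nBeams),
                 footprintDiameterM = footprintDiameterM,
                 overpassAzimuths = as.numeric(overpassAzimuths),
                 seed = as.integer(seed)),
            class = "orbitSpec")
}

#' Simulate footprint centre geometry along orbital tracks
#'
#' Places shots every `alongTrackSpacingM` metres along each beam line of
#' each overpass, numbering shots sequentially within each beam; footprints
#' outside the extent are dropped.  Only geometry is produced — metrics are
#' attached afterwards by [sampleFootprints()].
#'
#' @param orbit an [orbitSpec()].
#' @param extent named numeric `c(xmin, xmax, ymin, ymax)` in metres.
#' @return data.frame with columns `shot_id` (0-based rank within beam),
#'   `beam` (e.g. `"BEAM03"`), `track` (overpass label), `x`, `y`.
#'   Empty (with a warning) when no track intersects the extent.
#' @examples
#' ex <- c(xmin = 0, xmax = 1000, ymin = 0, ymax = 10000)
#' orb <- orbitSpec(nBeams = 1L, swathWidthM = 600, overpassAzimuths = 0)
#' nrow(simulateTracks(orb, ex))   # floor(10000/60) + 1 = 167
#' @export
simulateTracks <- function(orbit, extent) {
  stopifnot(inherits(orbit, "orbitSpec"))
  extent <- checkExtent(extent)
  if (length(orbit$overpassAzimuths) == 0L) {
    return(emptyGeomTable())
  }
  set.seed(orbit$seed)
  cx <- mean(extent[c("xmin", "xmax")])
  cy <- mean(extent[c("ymin", "ymax")])
  w2 <- (extent[["xmax"]] - extent[["xmin"]]) / 2
  h2 <- (extent[["ymax"]] - extent[["ymin"]]) / 2
  beamOffsets <- (seq_len(orbit$nBeams) - (orbit$nBeams + 1) / 2) *
    orbit$crossTrackSpacingM
  rows <- list()
  for (i in seq_along(orbit$overpassAzimuths)) {
    az <- orbit$overpassAzimuths[i] * pi / 180
    ## unit vector along track (azimuth from north, clockwise) and its
    ## perpendicular; swath centre offset drawn across the extent
    ux <- sin(az); uy <- cos(az)
    px <- cos(az); py <- -sin(az)
    ## swath centre offset drawn across the extent's perpendicular span,
    ## so every overpass crosses the scene
    span <- abs(w2 * px) + abs(h2 * py)
    off0 <- stats::runif(1, -span, span)
    for (b in seq_len(orbit$nBeams)) {
      off <- off0 + beamOffsets[b]
      ## beam line: (cx,cy) + off * perp + t * u ; clip t to the extent
      x0 <- cx + off * px
      y0 <- cy + off * py
      tr <- clipLineToRect(x0, y0, ux, uy, extent)
      if (is.null(tr)) next
      ## inset a hair so clipped endpoints never round outside the extent
      tr <- tr + c(1e-6, -1e-6)
      len <- tr[2] - tr[1]
      if (len < 0) next
      s <- seq(0, len, by = orbit$alongTrackSpacingM)
      rows[[length(rows) + 1L]] <- data.frame(
        shot_id = seq_along(s) - 1L,
        beam = sprintf("BEAM%02d", b),
        track = sprintf("T%02d", i),
        x = x0 + (tr[1] + s) * ux,
        y = y0 + (tr[1] + s) * uy)
    }
  }
  if (!length(rows)) {
    warning("no track intersects the extent; returning an empty table")
    return(emptyGeomTable())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

emptyGeomTable <- function() {
  data.frame(shot_id = integer(), beam = character(), track = character(),
             x = numeric(), y = numeric())
}

## intersect the parametric line (x0,y0)+t(ux,uy) with the extent rectangle;
## returns c(tmin, tmax) or NULL
clipLineToRect <- function(x0, y0, ux, uy, extent) {
  tmin <- -Inf
  tmax <- Inf
  for (dim in 1:2) {
    p0 <- if (dim == 1) x0 else y0
    u <- if (dim == 1) ux else uy
    lo <- extent[[if (dim == 1) "xmin" else "ymin"]]
    hi <- extent[[if (dim == 1) "xmax" else "ymax"]]
    if (abs(u) < 1e-12) {
      if (p0 < lo || p0 > hi) return(NULL)
    } else {
      t1 <- (lo - p0) / u
      t2 <- (hi - p0) / u
      tmin <- max(tmin, min(t1, t2))
      tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmin > tmax) NULL else c(tmin, tmax)
}

#' The 14 footprint metrics of the L2B schema
#'
#' Canopy cover, ground elevation, foliage height diversity, ancillary
#' Landsat/MODIS cover fractions, leaf-on/off day-of-year, plant area
#' index, directional gap probability, ground/vegetation return integrals,
#' maximum canopy height and waveform sensitivity.
#'
#' @return character vector of the 14 metric column names.
#' @export
gediMetricNames <- function() {
  c("cover", "dem", "fhd_normal", "landsat_treecover", "leaf_off_doy",
    "leaf_on_doy", "modis_treecover", "modis_nonvegetated", "pai",
    "pgap_thea", "rg", "rh100", "rv", "sensitivity")
}

#' Attach metric values and quality flags to footprint geometry
#'
#' Reads each metric from its field at the cell containing the footprint
#' (exact lookup when `noiseFrac = 0`), adds independent Gaussian
#' measurement noise with standard deviation `noiseFrac * sqrt(sill)`
#' (estimated as the field's empirical SD), and assigns the three quality
#' fields so that a configured fraction of shots violates each filtering
#' criterion: `quality_flag` 0 instead of 1, `degrade_flag` 1 instead of 0,
#' and `sensitivity` redrawn uniformly below 0.9.
#'
#' @param geom footprint geometry from [simulateTracks()].
#' @param fields named list of [RasterGrid-class] metric fields covering
#'   every footprint.
#' @param contamination named list/vector with elements `quality`,
#'   `degrade`, `sensitivity` in \[0, 1\] (default all 0).
#' @param noiseFrac measurement-noise SD as a fraction of each field's SD.
#' @param seed integer seed.
#' @return footprint data.frame: geometry columns, one column per metric,
#'   plus `quality_flag` and `degrade_flag`.
#' @export
sampleFootprints <- function(geom, fields,
                             contamination = c(quality = 0, degrade = 0,
                                               sensitivity = 0),
                             noiseFrac = 0, seed = 1L) {
  contamination <- as.list(contamination)
  for (k in c("quality", "degrade", "sensitivity")) {
    if (is.null(contamination[[k]])) contamination[[k]] <- 0
    if (contamination[[k]] < 0 || contamination[[k]] > 1) {
      stop("contamination fractions must lie in [0, 1]")
    }
  }
  out <- geom
  n <- nrow(geom)
  set.seed(seed)
  for (m in names(fields)) {
    v <- valueAtXY(fields[[m]], geom$x, geom$y)
    if (anyNA(v)) stop("footprint outside field extent for metric ", m)
    if (noiseFrac > 0) {
      v <- v + stats::rnorm(n, 0, noiseFrac * stats::sd(gridValues(fields[[m]])))
    }
    out[[m]] <- v
  }
  out$quality_flag <- ifelse(stats::runif(n) < contamination$quality, 0L, 1L)
  out$degrade_flag <- ifelse(stats::runif(n) < contamination$degrade, 1L, 0L)
  if ("sensitivity" %in% names(fields)) {
    bad <- stats::runif(n) < contamination$sensitivity
    out$sensitivity[bad] <- stats::runif(sum(bad), 0.5, 0.9)
  }
  out
}
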