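#' Validate a footprint table
#'
#' Checks the tabular contract shared by the whole pipeline: geometry
#' columns `shot_id`, `beam`, `track`, `x`, `y`, the metric columns of the
#' configured schema, and the quality fields `quality_flag` and
#' `degrade_flag` (the third quality value, `sensitivity`, is itself one of
#' the 14 metrics).  Coordinates must be finite.
#'
#' @param table data.frame to validate.
#' @param metrics expected metric schema (default [gediMetricNames()]).
#' @param requireQuality whether the quality fields must be present.
#' @return `table`, invisibly; errors describe the first violation.
#' @export
assertFootprintTable <- function(table, metrics = gediMetricNames(),
                                 requireQuality = TRUE) {
  need <- c("shot_id", "beam", "track", "x", "y", metrics)
  if (requireQuality) need <- c(need, "quality_flag", "degrade_flag")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("footprint table missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(table) && (any(!is.finite(table$x)) || any(!is.finite(table$y)))) {
    stop("footprint coordinates must be finite")
  }
  invisible(table)
}

#' Write / read footprint tables as CSV
#'
#' Plain CSV with the column order geometry, 14 metrics, quality flags.
#' Values round-trip bit-exactly (written at full double precision).
#'
#' @param table footprint data.frame.
#' @param path CSV path.
#' @param metrics metric schema.
#' @return `path` (writer) or the table (reader).
#' @export
writeFootprintsCSV <- function(table, path, metrics = gediMetricNames()) {
  assertFootprintTable(table, metrics)
  cols <- c("shot_id", "beam", "track", "x", "y", metrics,
            "quality_flag", "degrade_flag")
  df <- table[cols]
  for (cl in names(df)) {
    if (is.double(df[[cl]])) df[[cl]] <- sprintf("%.17g", df[[cl]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFootprintsCSV
#' @export
readFootprintsCSV <- function(path, metrics = gediMetricNames()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assertFootprintTable(df, metrics)
  df
}

#' Write footprints as GeoJSON points
#'
#' One point Feature per shot with all metric and quality values as
#' properties.  Coordinates are emitted as-is (planar metres in synthetic
#' mode, lon/lat for projected real data).
#'
#' @param table footprint data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFootprintsGeoJSON <- function(table, path) {
  props <- setdiff(names(table), c("x", "y"))
  feats <- lapply(seq_len(nrow(table)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(table$x[i], table$y[i])),
         properties = as.list(table[i, props, drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read GEDI L2B beam groups from an HDF5 granule
#'
#' Reads one dataset per requested metric from each `BEAMxxxx` group of an
#' L2B-style HDF5 file, plus `shot_number` and the geolocation datasets.
#' The read is delegated to the `h5py` Python library through a
#' subprocess, so a `python` interpreter with `h5py` must be on the PATH;
#' this reader is a real-data convenience and is not needed by the
#' synthetic workflow.
#'
#' @param path HDF5 granule path.
#' @param beams character vector of beam group names (e.g. `"BEAM0000"`).
#' @param metrics metric dataset names within each beam group.
#' @param lonDataset,latDataset geolocation dataset names within each beam
#'   group, mapped to `x` and `y`.
#' @param python python interpreter to use.
#' @return footprint data.frame (one row per shot, `track` set to the file
#'   base name).
#' @export
readL2B <- function(path, beams, metrics = gediMetricNames(),
                    lonDataset = "geolocation/lon_lowestmode",
                    latDataset = "geolocation/lat_lowestmode",
                    python = Sys.which("python")) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!nzchar(python)) stop("no python interpreter found for the h5py reader")
  datasets <- c("shot_number", lonDataset, latDataset, metrics,
                "quality_flag", "degrade_flag")
  colnames <- c("shot_id", "x", "y", metrics, "quality_flag", "degrade_flag")
  out <- tempfile(fileext = ".csv")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json, csv, h5py",
    "cfg = json.load(open(sys.argv[1]))",
    "f = h5py.File(cfg['path'], 'r')",
    "w = csv.writer(open(cfg['out'], 'w', newline=''))",
    "w.writerow(['beam'] + cfg['cols'])",
    "for beam in cfg['beams']:",
    "    if beam not in f:",
    "        sys.exit('format error: missing group ' + beam)",
    "    g = f[beam]",
    "    cols = []",
    "    for d in cfg['datasets']:",
    "        if d not in g:",
    "            sys.exit('format error: missing dataset %s/%s' % (beam, d))",
    "        cols.append(g[d][()])",
    "    for row in zip(*cols):",
    "        w.writerow([beam] + [repr(float(v)) for v in row])"
  ), script)
  cfg <- tempfile(fileext = ".json")
  jsonlite::write_json(list(path = path, out = out, beams = as.list(beams),
                            datasets = as.list(datasets),
                            cols = as.list(colnames)),
                       cfg, auto_unbox = TRUE)
  res <- suppressWarnings(system2(python, c(script, cfg),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    stop("L2B read failed: ", paste(res, collapse = "; "))
  }
  df <- utils::read.csv(out, stringsAsFactors = FALSE)
  df$track <- sub("\\.h5$", "", basename(path))
  assertFootprintTable(df, metrics)
  df[c("shot_id", "beam", "track", "x", "y", metrics,
       "quality_flag", "degrade_flag")]
}

#' Quality-filter criteria for footprints
#'
#' The standard forest criteria: `quality_flag` equal to 1, `degrade_flag`
#' equal to 0, and waveform sensitivity of at least 0.9.
#'
#' @param qualityFlagRequired required `quality_flag` value (default 1).
#' @param degradeFlagRequired required `degrade_flag` value (default 0).
#' @param sensitivityMin minimum sensitivity in \[0, 1\] (default 0.9).
#' @return object of class `filterCriteria`.
#' @export
filterCriteria <- function(qualityFlagRequired = 1L,
                           degradeFlagRequired = 0L,
                           sensitivityMin = 0.9) {
  if (sensitivityMin < 0 || sensitivityMin > 1) {
    stop("sensitivityMin must lie in [0, 1]")
  }
  structure(list(qualityFlagRequired = as.integer(qualityFlagRequired),
                 degradeFlagRequired = as.integer(degradeFlagRequired),
                 sensitivityMin = sensitivityMin),
            class = "filterCriteria")
}

#' Filter footprints on quality flags and sensitivity
#'
#' Keeps records with `quality_flag == required`, `degrade_flag ==
#' required` and `sensitivity >= sensitivityMin`, preserving order.  The
#' number of records failing each criterion (non-exclusively) is attached
#' as the `"filterReport"` attribute.  Filtering is idempotent.
#'
#' @param table footprint data.frame with the three quality fields.
#' @param criteria a [filterCriteria()].
#' @return the filtered table, possibly empty.
#' @export
filterFootprints <- function(table, criteria = filterCriteria()) {
  stopifnot(inherits(criteria, "filterCriteria"))
  need <- c("quality_flag", "degrade_flag", "sensitivity")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("table lacks quality fields: ",
                         paste(miss, collapse = ", "))
  passQ <- table$quality_flag == criteria$qualityFlagRequired
  passD <- table$degrade_flag == criteria$degradeFlagRequired
  passS <- table$sensitivity >= criteria$sensitivityMin
  keep <- passQ & passD & passS
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filterReport") <- list(
    n_input = nrow(table), n_kept = sum(keep),
    removed_quality_flag = sum(!passQ),
    removed_degrade_flag = sum(!passD),
    removed_sensitivity = sum(!passS),
    criteria = unclass(criteria))
  out
}

#' Write the filter report of a filtered table as JSON
#' @param table output of [filterFootprints()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
writeFilterReport <- function(table, path) {
  rep <- attr(table, "filterReport")
  if (is.null(rep)) stop("table has no filterReport attribute")
  jsonlite::write_json(rep, path, auto_unbox = TRUE)
  invisible(path)
}

#' Thin footprints at a fixed shot interval
#'
#' Orders shots by `shot_id` within each beam line (beam x track by
#' default, the pooled stream with `perBeam = FALSE`) and keeps those
#' whose 0-based rank is congruent to `offset` modulo `interval`.
#' `interval = 1` is the identity.  With `random = TRUE` the offset is
#' drawn uniformly per beam line from `0:(interval-1)` under `seed`,
#' reproducing interval thinning with a random phase.
#'
#' @param table footprint data.frame.
#' @param interval keep every `interval`-th shot (>= 1).
#' @param offset 0-based rank offset (default 0).
#' @param perBeam thin within each (track, beam) line (default) or over
#'   the pooled ordered stream.
#' @param random draw a random per-line offset instead of `offset`.
#' @param seed seed for `random = TRUE`.
#' @return the thinned table, original order preserved.
#' @examples
#' t <- data.frame(shot_id = 0:136, beam = "BEAM01", track = "T01",
#'                 x = 0, y = 0)
#' nrow(thinFootprints(t, 100))   # ranks 0 and 100 -> 2
#' @export
thinFootprints <- function(table, interval, offset = 0L, perBeam = TRUE,
                           random = FALSE, seed = 1L) {
  if (length(interval) != 1L || !is.finite(interval) || interval < 1) {
    stop("invalid argument: interval must be an integer >= 1")
  }
  interval <- as.integer(interval)
  if (!nrow(table)) return(table)
  group <- if (perBeam) paste(table$track, table$beam) else
    rep("all", nrow(table))
  if (random) set.seed(seed)
  keep <- logical(nrow(table))
  for (g in unique(group)) {
    idx <- which(group == g)
    idx <- idx[order(table$shot_id[idx])]
    off <- if (random) sample.int(interval, 1L) - 1L else
      as.integer(offset) %% interval
    rank <- seq_along(idx) - 1L
    keep[idx[rank %% interval == off]] <- TRUE
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
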