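#' Default metric-field parameters for the synthetic scene
#'
#' Means and sills (variances) for the 14 L2B metrics, chosen at
#' magnitudes typical of montane conifer forest: canopy cover and gap
#' probability as proportions, PAI in m2/m2, rh100 in metres, DEM in
#' metres a.s.l., day-of-year metrics in days, waveform integrals in
#' arbitrary energy counts and sensitivity close to 1.
#'
#' The `loading` column is the latent canopy-density share of each metric
#' (see [fieldSpec()]): the canopy-structure metrics load strongly
#' (negatively for gap probability, ground energy and the non-vegetated
#' fraction), terrain elevation and phenology dates load zero.
#'
#' @return data.frame with columns `metric`, `mean`, `sill`, `loading`.
#' @export
defaultFieldParams <- function() {
  data.frame(
    metric = gediMetricNames(),
    mean = c(0.6, 3400, 2.5, 60, 300, 120, 55, 10, 2.5, 0.35, 2500, 28,
             3000, 0.95),
    sill = c(0.02, 40000, 0.09, 100, 100, 100, 100, 25, 0.25, 0.01,
             250000, 25, 250000, 0.0004),
    loading = c(0.85, 0, 0.8, 0.7, 0, 0, 0.6, -0.5, 0.85, -0.85, -0.8,
                0.7, 0.6, 0.3))
}

## deterministic per-stage seed derived from the global seed and the stage
## name (polynomial hash mod a Mersenne prime, kept below 2^31)
stageSeed <- function(globalSeed, stage) {
  p <- 2147483647
  h <- as.numeric(globalSeed) %% p
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% p
  as.integer(h)
}

#' Simulate a complete synthetic study scene
#'
#' One call producing everything the downstream pipeline consumes: the 14
#' autocorrelated metric fields, the crossing-track footprint geometry,
#' contaminated footprint records, and field plots with tree lists whose
#' biomass is coupled to five canopy-structure fields (cover, fhd_normal,
#' pai positively; pgap_thea, rg negatively).  All sub-generators receive
#' seeds derived deterministically from `seed`.
#'
#' The defaults emulate the study conditions: a 20 x 20 km extent, 50
#' crossing overpasses of 8 beams (60 m along-track, 600 m cross-track
#' spacing), quality contamination of 5%/2%/5%, 138 plots, and coupling
#' noise equal to 30% of the AGB standard deviation (45 t/hm^2 around a
#' 100 t/hm^2 mean).
#'
#' @param seed integer master seed.
#' @param extent scene extent `c(xmin, xmax, ymin, ymax)` in metres.
#' @param resolutionM metric-field grid resolution (m).
#' @param overpassAzimuths track azimuths (degrees), one overpass each.
#' @param contamination named fractions for `quality`, `degrade`,
#'   `sensitivity` flag contamination.
#' @param noiseFrac footprint measurement-noise SD as a fraction of each
#'   field's SD.
#' @param nPlots number of field plots.
#' @param agbMean,agbSd mean and SD (t/hm^2) of the latent plot AGB.
#' @param couplingNoiseFrac coupling noise SD as a fraction of `agbSd`.
#' @param rangeM,nugget spatial covariance parameters of the fields.
#' @return list with `fields`, `footprints`, `plots`, `trees`, and the
#'   specs used (`fieldSpec`, `orbitSpec`, `plotSpec`).
#' @export
simulateScene <- function(seed = 1L,
                          extent = c(xmin = 0, xmax = 20000,
                                     ymin = 0, ymax = 20000),
                          resolutionM = 60,
                          overpassAzimuths = seq(0, 176.4, length.out = 50),
                          contamination = c(quality = 0.05, degrade = 0.02,
                                            sensitivity = 0.05),
                          noiseFrac = 0.05, nPlots = 138L, agbMean = 100,
                          agbSd = 45, couplingNoiseFrac = 0.3,
                          rangeM = 3000, nugget = 0.05) {
  fp <- defaultFieldParams()
  means <- stats::setNames(fp$mean, fp$metric)
  sills <- stats::setNames(fp$sill, fp$metric)
  loadings <- stats::setNames(fp$loading, fp$metric)
  fSpec <- fieldSpec(extent, means, sills, rangeM = rangeM,
                     nugget = nugget, latentShare = loadings,
                     seed = stageSeed(seed, "fields"))
  fields <- generateField(fSpec, resolutionM)
  oSpec <- orbitSpec(overpassAzimuths = overpassAzimuths,
                     seed = stageSeed(seed, "tracks"))
  geom <- simulateTracks(oSpec, extent)
  footprints <- sampleFootprints(geom, fields, contamination,
                                 noiseFrac = noiseFrac,
                                 seed = stageSeed(seed, "sampling"))
  ## AGB coupled to five structure metrics with equal weights on the
  ## standardised scale; the normalisation accounts for the metrics'
  ## latent cross-correlation so the coupled part has SD agbSd
  coupled <- c(cover = 1, fhd_normal = 1, pai = 1, pgap_thea = -1, rg = -1)
  a <- loadings[names(coupled)]
  corr <- outer(a, a)
  diag(corr) <- 1
  norm <- sqrt(drop(coupled %*% corr %*% coupled))
  coef <- coupled * agbSd / (norm * sqrt(sills[names(coupled)]))
  intercept <- agbMean - sum(coef * means[names(coupled)])
  pSpec <- plotSimSpec(nPlots = nPlots,
                       coupling = list(intercept = intercept, coef = coef,
                                       noiseSd = couplingNoiseFrac * agbSd),
                       seed = stageSeed(seed, "plots"))
  sim <- simulatePlots(pSpec, fields)
  list(fields = fields, footprints = footprints, plots = sim$plots,
       trees = sim$trees,
       specs = list(fieldSpec = fSpec, orbitSpec = oSpec, plotSpec = pSpec))
}

#' Default synthetic run configuration
#'
#' A nested configuration covering every pipeline stage.  All values can
#' be overridden (e.g. a smaller extent for quick runs); the seed is
#' mandatory and drives deterministically derived per-stage seeds.
#'
#' @param seed integer master seed.
#' @return nested list of class `runConfig`.
#' @export
defaultRunConfig <- function(seed = 1L) {
  structure(list(
    mode = "synthetic",
    seed = as.integer(seed),
    scene = list(extent = c(xmin = 0, xmax = 20000, ymin = 0, ymax = 20000),
                 resolution_m = 60, n_overpasses = 50,
                 contamination = c(quality = 0.05, degrade = 0.02,
                                   sensitivity = 0.05),
                 noise_frac = 0.05, n_plots = 138,
                 coupling_noise_frac = 0.3),
    filter = list(quality = 1, degrade = 0, sensitivity_min = 0.9),
    thin = list(interval = 100, per_beam = TRUE),
    interpolation = list(power = 2, n_neighbors = 12, resolution_m = 60,
                         intervals = c(10, 30, 50, 70, 100),
                         fraction = 0.7),
    modeling = list(algorithm = "rf", top_k = 5, n_folds = 10,
                    ntree = 300, mtry = 2, cost = 1, gamma = 0.92, k = 9)
  ), class = "runConfig")
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @return a `runConfig` list (reader) or `path` (writer).
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$scene$extent)) {
    cfg$scene$extent <- unlist(cfg$scene$extent)
  }
  if (!is.null(cfg$scene$contamination)) {
    cfg$scene$contamination <- unlist(cfg$scene$contamination)
  }
  structure(cfg, class = "runConfig")
}

#' @rdname readRunConfig
#' @param config a `runConfig` list.
#' @export
writeRunConfig <- function(config, path) {
  cfg <- unclass(config)
  ## named vectors become YAML maps so names survive the round trip
  if (!is.null(cfg$scene$extent)) cfg$scene$extent <- as.list(cfg$scene$extent)
  if (!is.null(cfg$scene$contamination)) {
    cfg$scene$contamination <- as.list(cfg$scene$contamination)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

validateRunConfig <- function(config) {
  need <- c("mode", "seed", "filter", "thin", "interpolation", "modeling")
  if (identical(config$mode, "synthetic")) need <- c(need, "scene")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    stop("run configuration missing section(s): ",
         paste(miss, collapse = ", "))
  }
  if (is.null(config$seed)) stop("run configuration: seed is mandatory")
  invisible(config)
}

#' Run the full footprint-to-biomass workflow
#'
#' Executes the five workflow steps in order — (1) quality filtering,
#' (2) thinning and IDW interpolation to surfaces, (3) interpolation
#' accuracy evaluation across sampling densities, (4) correlation
#' screening of variables against plot biomass, (5) biomass model
#' cross-validation and wall-to-wall mapping — writing each stage's
#' artifacts into `outDir` before the next stage starts, and finally a
#' run manifest with file digests, versions and timings.
#'
#' In `"synthetic"` mode the scene is simulated from the configuration;
#' in `"real"` mode `config$input$footprints_csv` and
#' `config$input$plots_csv` provide the data.
#'
#' @param config a `runConfig` (see [defaultRunConfig()]).
#' @param outDir output directory (created if absent).
#' @return the run manifest, invisibly (also written as
#'   `manifest.json`).
#' @export
runPipeline <- function(config, outDir) {
  validateRunConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  files <- character()
  tick <- function(stage, start) {
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - start, 3)
  }

  ## stage 0/1: data acquisition + quality filtering
  ts <- proc.time()[["elapsed"]]
  if (identical(config$mode, "synthetic")) {
    sc <- config$scene
    scene <- simulateScene(
      seed = config$seed, extent = sc$extent,
      resolutionM = sc$resolution_m,
      overpassAzimuths = seq(0, 180 * (1 - 1 / sc$n_overpasses),
                             length.out = sc$n_overpasses),
      contamination = sc$contamination, noiseFrac = sc$noise_frac,
      nPlots = sc$n_plots, couplingNoiseFrac = sc$coupling_noise_frac)
    footprints <- scene$footprints
    plots <- scene$plots
    files["footprints"] <- writeFootprintsCSV(
      footprints, file.path(outDir, "footprints.csv"))
    utils::write.csv(plots, file.path(outDir, "plots.csv"),
                     row.names = FALSE)
    files["plots"] <- file.path(outDir, "plots.csv")
  } else {
    footprints <- readFootprintsCSV(config$input$footprints_csv)
    tt <- readTreeTable(config$input$plots_csv)
    plots <- plotAGB(tt$trees, tt$plots)
  }
  crit <- filterCriteria(config$filter$quality, config$filter$degrade,
                         config$filter$sensitivity_min)
  filtered <- filterFootprints(footprints, crit)
  files["filtered"] <- writeFootprintsCSV(
    filtered, file.path(outDir, "footprints_filtered.csv"))
  files["filter_report"] <- writeFilterReport(
    filtered, file.path(outDir, "filter_report.json"))
  tick("filter", ts)

  ## stage 2: thinning + interpolation to surfaces
  ts <- proc.time()[["elapsed"]]
  thinned <- thinFootprints(filtered, config$thin$interval,
                            perBeam = isTRUE(config$thin$per_beam))
  files["thinned"] <- writeFootprintsCSV(
    thinned, file.path(outDir, "footprints_thinned.csv"))
  params <- idwParams(power = config$interpolation$power,
                      nNeighbors = config$interpolation$n_neighbors)
  ext <- extentOf(footprints)
  surfaces <- idwRasterize(thinned, gediMetricNames(), ext,
                           config$interpolation$resolution_m, params)
  rasterDir <- file.path(outDir, "surfaces")
  dir.create(rasterDir, showWarnings = FALSE)
  for (v in names(surfaces)) {
    files[paste0("surface_", v)] <- writeAsciiGrid(
      surfaces[[v]], file.path(rasterDir, paste0(v, ".asc")))
  }
  tick("interpolate", ts)

  ## stage 3: density sensitivity experiment
  ts <- proc.time()[["elapsed"]]
  experiment <- runDensityExperiment(
    filtered, intervals = config$interpolation$intervals,
    fraction = config$interpolation$fraction, params = params,
    seed = stageSeed(config$seed, "experiment"))
  writeDensityExperiment(experiment,
                         csvPath = file.path(outDir, "density_experiment.csv"),
                         jsonPath = file.path(outDir, "density_experiment.json"))
  files["experiment_csv"] <- file.path(outDir, "density_experiment.csv")
  files["experiment_json"] <- file.path(outDir, "density_experiment.json")
  tick("experiment", ts)

  ## stage 4: correlation screening
  ts <- proc.time()[["elapsed"]]
  fm <- extractFeatures(plots, surfaces)
  screen <- correlationScreen(fm, topK = config$modeling$top_k)
  utils::write.csv(screen, file.path(outDir, "screening.csv"),
                   row.names = FALSE)
  files["screening"] <- file.path(outDir, "screening.csv")
  tick("screen", ts)

  ## stage 5: biomass modelling + wall-to-wall map
  ts <- proc.time()[["elapsed"]]
  cfg <- modelConfig(config$modeling$algorithm,
                     ntree = config$modeling$ntree,
                     mtry = config$modeling$mtry,
                     cost = config$modeling$cost,
                     gamma = config$modeling$gamma,
                     k = config$modeling$k,
                     seed = stageSeed(config$seed, "modeling"))
  selected <- screen$variable[screen$selected]
  cv <- fitAndCrossValidate(fm, selected, cfg,
                            nFolds = config$modeling$n_folds)
  jsonlite::write_json(
    list(algorithm = cfg$algorithm, variables = selected,
         fold_metrics = cv$fold_metrics,
         mean_metrics = cv$mean_metrics,
         pooled_metrics = unclass(cv$pooled_metrics)),
    file.path(outDir, "cv_results.json"), auto_unbox = TRUE, digits = NA)
  files["cv_results"] <- file.path(outDir, "cv_results.json")
  mapped <- predictMap(cv, surfaces)
  files["agb_map"] <- writeAsciiGrid(mapped$map,
                                     file.path(outDir, "agb_map.asc"))
  jsonlite::write_json(mapped$summary, file.path(outDir, "agb_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  files["agb_summary"] <- file.path(outDir, "agb_summary.json")
  tick("model", ts)

  manifest <- list(
    config = unclass(config),
    config_digest = digestConfig(config),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    names(files))),
    versions = list(package = as.character(utils::packageVersion("gediBiomass")),
                    r = paste(R.version$major, R.version$minor, sep = ".")),
    timings_s = c(timings,
                  total = round(proc.time()[["elapsed"]] - t0, 3)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

extentOf <- function(table) {
  c(xmin = min(table$x), xmax = max(table$x),
    ymin = min(table$y), ymax = max(table$y))
}

digestConfig <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}
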