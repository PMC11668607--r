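#' Specification of synthetic field plots
#'
#' Describes how inventory plots with individual tree lists are simulated.
#' A target AGB density is first drawn for each plot by a linear coupling
#' to the metric fields at the plot location plus Gaussian noise; a tree
#' list (lognormal DBH, Chapman–Richards height curve with multiplicative
#' lognormal noise, Bernoulli species mix) is then grown tree by tree until
#' its allometric biomass reaches the target, so plot AGB always equals the
#' allometry module applied to the same tree list and matches the target up
#' to one-tree discretisation.
#'
#' @param nPlots number of plots.
#' @param plotAreaHm2 plot area in hectares (> 0).
#' @param stemsRange integer `c(min, max)`: `max` caps the tree list;
#'   `min` is used only when no coupling is given.
#' @param dbhMeanlog,dbhSdlog lognormal DBH parameters (cm).
#' @param heightA,heightB,heightC Chapman–Richards height curve
#'   `H = 1.3 + A (1 - exp(-B D))^C` (m, with D in cm).
#' @param heightSdlog SD of the multiplicative lognormal height noise.
#' @param spruceFraction probability a tree is spruce (else fir), in \[0,1\].
#' @param coupling `NULL`, or a list with `intercept` (t/hm^2), `coef`
#'   (named numeric: t/hm^2 per metric unit) and `noiseSd` (t/hm^2) linking
#'   plot AGB to the local metric-field values.
#' @param seed integer seed.
#' @return object of class `plotSimSpec`.
#' @export
plotSimSpec <- function(nPlots = 138L, plotAreaHm2 = 0.0667,
                        stemsRange = c(5L, 200L),
                        dbhMeanlog = log(22), dbhSdlog = 0.4,
                        heightA = 30, heightB = 0.05, heightC = 1.3,
                        heightSdlog = 0.1, spruceFraction = 0.6,
                        coupling = NULL, seed = 1L) {
  if (plotAreaHm2 <= 0) stop("invalid specification: plotAreaHm2 must be > 0")
  if (spruceFraction < 0 || spruceFraction > 1) {
    stop("invalid specification: spruceFraction must lie in [0, 1]")
  }
  if (!is.null(coupling)) {
    stopifnot(is.list(coupling), !is.null(coupling$coef),
              !is.null(names(coupling$coef)))
    if (is.null(coupling$intercept)) coupling$intercept <- 0
    if (is.null(coupling$noiseSd)) coupling$noiseSd <- 0
    if (coupling$noiseSd < 0) stop("coupling noiseSd must be >= 0")
  }
  structure(list(nPlots = as.integer(nPlots), plotAreaHm2 = plotAreaHm2,
                 stemsRange = as.integer(stemsRange),
                 dbhMeanlog = dbhMeanlog, dbhSdlog = dbhSdlog,
                 heightA = heightA, heightB = heightB, heightC = heightC,
                 heightSdlog = heightSdlog, spruceFraction = spruceFraction,
                 coupling = coupling, seed = as.integer(seed)),
            class = "plotSimSpec")
}

#' Simulate field plots with tree lists
#'
#' Plot locations are uniform over the field extent.  With a coupling, the
#' target density for plot i is
#' `intercept + sum_j coef_j * field_j(x_i, y_i) + N(0, noiseSd)`,
#' truncated below at 0; trees are appended until the plot's allometric
#' biomass reaches the target or the stem cap is hit.  Without a coupling,
#' each plot receives a uniform number of stems in `stemsRange`.
#'
#' @param spec a [plotSimSpec()].
#' @param fields named list of [RasterGrid-class] metric fields (must
#'   contain every metric named in the coupling).
#' @return list with `plots` (plot_id, x, y, area_hm2, target_agb_t_hm2,
#'   agb_t_hm2) and `trees` (plot_id, species, dbh_cm, height_m).
#' @export
simulatePlots <- function(spec, fields) {
  stopifnot(inherits(spec, "plotSimSpec"), length(fields) >= 1L)
  ex <- gridExtent(fields[[1L]])
  set.seed(spec$seed)
  n <- spec$nPlots
  px <- stats::runif(n, ex["xmin"], ex["xmax"])
  py <- stats::runif(n, ex["ymin"], ex["ymax"])
  target <- rep(NA_real_, n)
  if (!is.null(spec$coupling)) {
    cf <- spec$coupling$coef
    miss <- setdiff(names(cf), names(fields))
    if (length(miss)) stop("coupling names missing from fields: ",
                           paste(miss, collapse = ", "))
    target <- rep(spec$coupling$intercept, n)
    for (m in names(cf)) {
      target <- target + cf[[m]] * valueAtXY(fields[[m]], px, py)
    }
    target <- target + stats::rnorm(n, 0, spec$coupling$noiseSd)
    target <- pmax(target, 0)
  }
  plotIds <- sprintf("P%03d", seq_len(n))
  treeRows <- vector("list", n)
  for (i in seq_len(n)) {
    if (is.null(spec$coupling)) {
      nStems <- sample(spec$stemsRange[1]:spec$stemsRange[2], 1L)
      trees <- drawTrees(spec, nStems)
    } else {
      targetMass <- target[i] * spec$plotAreaHm2 * 1000  # kg in the plot
      trees <- drawTrees(spec, spec$stemsRange[2])
      cum <- cumsum(treeAGB(trees$species, trees$dbh_cm, trees$height_m))
      keep <- which(cum >= targetMass)[1]
      if (is.na(keep)) keep <- nrow(trees)          # stem cap reached
      if (targetMass <= 0) keep <- 0L
      trees <- trees[seq_len(keep), , drop = FALSE]
    }
    if (nrow(trees)) trees$plot_id <- plotIds[i]
    treeRows[[i]] <- trees
  }
  trees <- do.call(rbind, treeRows[vapply(treeRows, nrow, 0L) > 0])
  if (is.null(trees)) {
    trees <- data.frame(plot_id = character(), species = character(),
                        dbh_cm = numeric(), height_m = numeric())
  } else {
    trees <- trees[c("plot_id", "species", "dbh_cm", "height_m")]
    rownames(trees) <- NULL
  }
  plots <- data.frame(plot_id = plotIds, x = px, y = py,
                      area_hm2 = spec$plotAreaHm2,
                      target_agb_t_hm2 = target)
  plots <- plotAGB(trees, plots)
  list(plots = plots, trees = trees)
}

drawTrees <- function(spec, nStems) {
  if (nStems <= 0) {
    return(data.frame(species = character(), dbh_cm = numeric(),
                      height_m = numeric()))
  }
  d <- stats::rlnorm(nStems, spec$dbhMeanlog, spec$dbhSdlog)
  h <- (1.3 + spec$heightA * (1 - exp(-spec$heightB * d))^spec$heightC) *
    stats::rlnorm(nStems, 0, spec$heightSdlog)
  sp <- ifelse(stats::runif(nStems) < spec$spruceFraction, "spruce", "fir")
  data.frame(species = sp, dbh_cm = d, height_m = h)
}

#' Write plot and tree tables as one flat CSV
#' @param sim output of [simulatePlots()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeTreeTable <- function(sim, path) {
  df <- merge(sim$trees,
              sim$plots[c("plot_id", "x", "y", "area_hm2")],
              by = "plot_id", sort = FALSE)
  df <- df[c("plot_id", "x", "y", "area_hm2", "species", "dbh_cm",
             "height_m")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
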