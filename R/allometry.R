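#' Single-tree aboveground biomass from binary allometric models
#'
#' Power-law biomass models for the two species of the spruce–fir forest
#' type, driven by diameter at breast height D (cm) and total tree height
#' H (m):
#' \deqn{M_{spruce} = 0.09152\, D^{2.21060} H^{0.25663}}
#' \deqn{M_{fir}    = 0.06127\, D^{2.05753} H^{0.50839}}
#' Following the Chinese forestry-standard convention the per-tree mass M is
#' in kilograms; [plotAGB()] converts to tonnes when aggregating to density.
#'
#' @param species character vector, `"spruce"` or `"fir"` (recycled against
#'   `dbh_cm`/`height_m`).
#' @param dbh_cm diameter at breast height in centimetres (> 0).
#' @param height_m tree height in metres (> 0).
#' @return numeric vector of per-tree aboveground biomass in kg.
#' @examples
#' treeAGB("spruce", 1, 1)   # the model's leading coefficient
#' treeAGB("fir", 30, 20)
#' @export
treeAGB <- function(species, dbh_cm, height_m) {
  n <- max(length(species), length(dbh_cm), length(height_m))
  species <- rep_len(as.character(species), n)
  dbh_cm <- rep_len(as.numeric(dbh_cm), n)
  height_m <- rep_len(as.numeric(height_m), n)
  if (any(!species %in% c("spruce", "fir"))) {
    stop("unsupported species: ",
         paste(unique(setdiff(species, c("spruce", "fir"))), collapse = ", "),
         " (models exist for 'spruce' and 'fir' only)")
  }
  if (any(!is.finite(dbh_cm)) || any(dbh_cm <= 0) ||
      any(!is.finite(height_m)) || any(height_m <= 0)) {
    stop("dbh_cm and height_m must be finite and strictly positive")
  }
  out <- numeric(n)
  sp <- species == "spruce"
  out[sp] <- 0.09152 * dbh_cm[sp]^2.21060 * height_m[sp]^0.25663
  out[!sp] <- 0.06127 * dbh_cm[!sp]^2.05753 * height_m[!sp]^0.50839
  out
}

#' Plot-level aboveground biomass density
#'
#' Sums per-tree biomass over each plot's tree list, converts kg to tonnes,
#' and divides by plot area to give AGB density in t/hm^2 (tonnes per
#' hectare).  A plot with no trees has density 0.
#'
#' @param trees data.frame with columns `plot_id`, `species`, `dbh_cm`,
#'   `height_m` (one row per tree; may be empty).
#' @param plots data.frame with columns `plot_id` and `area_hm2` (> 0);
#'   optional extra columns (e.g. `x`, `y`) are carried through.
#' @return `plots` with an added `agb_t_hm2` column.
#' @examples
#' plots <- data.frame(plot_id = "p1", area_hm2 = 1)
#' trees <- data.frame(plot_id = "p1", species = "spruce",
#'                     dbh_cm = 1, height_m = 1)
#' plotAGB(trees, plots)$agb_t_hm2   # 9.152e-05
#' @export
plotAGB <- function(trees, plots) {
  stopifnot(all(c("plot_id", "area_hm2") %in% names(plots)))
  if (any(!is.finite(plots$area_hm2)) || any(plots$area_hm2 <= 0)) {
    stop("plot area_hm2 must be finite and strictly positive")
  }
  mass_t <- rep(0, nrow(plots))
  if (nrow(trees)) {
    stopifnot(all(c("plot_id", "species", "dbh_cm", "height_m") %in%
                    names(trees)))
    kg <- treeAGB(trees$species, trees$dbh_cm, trees$height_m)
    agg <- tapply(kg, factor(trees$plot_id, levels = plots$plot_id), sum)
    agg[is.na(agg)] <- 0
    mass_t <- as.numeric(agg) / 1000
  }
  plots$agb_t_hm2 <- mass_t / plots$area_hm2
  plots
}

#' Read a field-plot tree table from CSV
#'
#' Expected columns: `plot_id`, `x`, `y`, `area_hm2`, `species`, `dbh_cm`,
#' `height_m` — one row per tree, with the plot location and area repeated.
#'
#' @param path CSV file path.
#' @return list with `plots` (one row per plot: plot_id, x, y, area_hm2)
#'   and `trees` (one row per tree).
#' @export
readTreeTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "x", "y", "area_hm2", "species", "dbh_cm", "height_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("tree table missing columns: ",
                         paste(miss, collapse = ", "))
  plots <- unique(df[c("plot_id", "x", "y", "area_hm2")])
  rownames(plots) <- NULL
  list(plots = plots,
       trees = df[c("plot_id", "species", "dbh_cm", "height_m")])
}
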