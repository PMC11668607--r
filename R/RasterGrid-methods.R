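#' Construct a RasterGrid
#'
#' @param values numeric matrix (row 1 = northernmost row).
#' @param originX,originY planar coordinates (m) of the upper-left corner.
#' @param cellSize cell edge length in metres.
#' @return A [RasterGrid-class] object.
#' @examples
#' g <- rasterGrid(matrix(1:6, 2, 3), 0, 2000, 1000)
#' dim(g)
#' @export
rasterGrid <- function(values, originX, originY, cellSize) {
  new("RasterGrid", originX = as.numeric(originX),
      originY = as.numeric(originY), cellSize = as.numeric(cellSize),
      values = values)
}

#' @describeIn rasterGrid grid dimensions as `c(nrow, ncol)`.
#' @param x a `RasterGrid`.
#' @export
setMethod("dim", "RasterGrid", function(x) dim(x@values))

#' @export
setMethod("show", "RasterGrid", function(object) {
  d <- dim(object@values)
  v <- object@values[is.finite(object@values)]
  cat(sprintf("RasterGrid: %d rows x %d cols, cell %g m\n", d[1], d[2],
              object@cellSize))
  cat(sprintf("  origin (UL): %g, %g;  extent %g x %g m\n",
              object@originX, object@originY,
              d[2] * object@cellSize, d[1] * object@cellSize))
  if (length(v)) {
    cat(sprintf("  values: [%g, %g], mean %g; %d nodata cells\n",
                min(v), max(v), mean(v), sum(!is.finite(object@values))))
  } else {
    cat("  values: all nodata\n")
  }
  invisible(object)
})

#' Grid values as a matrix
#' @param x a `RasterGrid`.
#' @return The numeric value matrix (row 1 = top).
#' @export
gridValues <- function(x) {
  stopifnot(is(x, "RasterGrid"))
  x@values
}

#' Extent of a RasterGrid
#' @param x a `RasterGrid`.
#' @return Named vector `c(xmin, xmax, ymin, ymax)` in metres.
#' @export
gridExtent <- function(x) {
  stopifnot(is(x, "RasterGrid"))
  d <- dim(x@values)
  c(xmin = x@originX, xmax = x@originX + d[2] * x@cellSize,
    ymin = x@originY - d[1] * x@cellSize, ymax = x@originY)
}

#' Cell-centre coordinates
#' @param x a `RasterGrid`.
#' @return data.frame with `row`, `col`, `x`, `y` for every cell, row-major.
#' @export
cellCenters <- function(x) {
  stopifnot(is(x, "RasterGrid"))
  d <- dim(x@values)
  col <- rep(seq_len(d[2]), times = d[1])
  row <- rep(seq_len(d[1]), each = d[2])
  data.frame(row = row, col = col,
             x = x@originX + (col - 0.5) * x@cellSize,
             y = x@originY - (row - 0.5) * x@cellSize)
}

#' Look up grid values at point locations
#'
#' Returns the value of the cell *containing* each point (no resampling,
#' matching the semantics of an IDW surface).  Points outside the grid
#' return `NA`.
#'
#' @param grid a `RasterGrid`.
#' @param x,y numeric vectors of planar coordinates (m).
#' @return numeric vector of cell values.
#' @export
valueAtXY <- function(grid, x, y) {
  stopifnot(is(grid, "RasterGrid"), length(x) == length(y))
  d <- dim(grid@values)
  col <- floor((x - grid@originX) / grid@cellSize) + 1L
  row <- floor((grid@originY - y) / grid@cellSize) + 1L
  ## points exactly on the east/south edge belong to the last cell
  col[col == d[2] + 1L & x <= grid@originX + d[2] * grid@cellSize] <- d[2]
  row[row == d[1] + 1L & y >= grid@originY - d[1] * grid@cellSize] <- d[1]
  ok <- col >= 1L & col <= d[2] & row >= 1L & row <= d[1]
  out <- rep(NA_real_, length(x))
  out[ok] <- grid@values[cbind(row[ok], col[ok])]
  out
}

#' Write a RasterGrid as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by standard GIS software.  `NA`
#' cells are written as the nodata value.
#'
#' @param grid a `RasterGrid`.
#' @param path output file path (conventionally `.asc`).
#' @param nodata nodata marker written for `NA` cells (default -9999).
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(grid, path, nodata = -9999) {
  stopifnot(is(grid, "RasterGrid"))
  d <- dim(grid@values)
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", grid@originX),
    sprintf("yllcorner %.10g", grid@originY - d[1] * grid@cellSize),
    sprintf("cellsize %.10g", grid@cellSize),
    sprintf("NODATA_value %.10g", nodata)
  )
  v <- grid@values
  v[!is.finite(v)] <- nodata
  rows <- apply(v, 1L, function(r) paste(format(r, digits = 15, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path path to an `.asc` file written by [writeAsciiGrid()] or a GIS.
#' @return A [RasterGrid-class]; nodata cells become `NA`.
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  body <- lines[i:length(lines)]
  vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l),
                                                       "[[:space:]]+")[[1]]))
  m <- do.call(rbind, vals)
  stopifnot(nrow(m) == hdr$nrows, ncol(m) == hdr$ncols)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  rasterGrid(m, hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize,
             hdr$cellsize)
}
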