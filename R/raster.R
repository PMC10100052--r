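#' Rectangular analysis window
#'
#' A site window is an axis-aligned rectangle in planar metre coordinates.
#' All point patterns, rasters and quadrature schemes in the package refer to
#' such a window.
#'
#' @param xmin,xmax,ymin,ymax window bounds in metres.
#' @return An object of class \code{"bbox_window"}: a named list with the four
#'   bounds.
#' @examples
#' w <- bbox_window(0, 1000, 0, 1000)
#' window_area(w)  # 1e6 m^2
#' @export
bbox_window <- function(xmin, xmax, ymin, ymax) {
  stopifnot(is.finite(xmin), is.finite(xmax), is.finite(ymin), is.finite(ymax))
  if (xmax <= xmin || ymax <= ymin)
    stop("window has non-positive extent")
  structure(list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
            class = "bbox_window")
}

#' @rdname bbox_window
#' @param window a \code{bbox_window}.
#' @export
window_area <- function(window) {
  (window$xmax - window$xmin) * (window$ymax - window$ymin)
}

#' @rdname bbox_window
#' @param x,y coordinates to test.
#' @return \code{inside_window} returns a logical vector.
#' @export
inside_window <- function(x, y, window) {
  x >= window$xmin & x <= window$xmax & y >= window$ymin & y <= window$ymax
}

#' Covariate surface on a regular metre grid
#'
#' A \code{grid_raster} stores one spatial covariate (habitat attractiveness
#' or playback proximity) as cell values on a regular grid, by default 10 m
#' cells. Cell (i, j) has its centre at
#' \code{(x0 + (j - 0.5) * cell, y0 + (i - 0.5) * cell)}; row 1 is the
#' southernmost row. Values must be finite.
#'
#' @param values numeric matrix of cell values, \code{nrow} rows (south to
#'   north) by \code{ncol} columns (west to east).
#' @param x0,y0 coordinates of the grid origin (south-west corner), metres.
#' @param cell cell side length in metres (> 0).
#' @return An object of class \code{"grid_raster"}.
#' @seealso [raster_from_window()], [sample_raster()], [read_esri_ascii()]
#' @export
grid_raster <- function(values, x0 = 0, y0 = 0, cell = 10) {
  values <- as.matrix(values)
  if (cell <= 0) stop("cell size must be positive")
  if (!all(is.finite(values))) stop("raster values must all be finite")
  structure(list(x0 = x0, y0 = y0, cell = cell,
                 nrow = nrow(values), ncol = ncol(values),
                 values = values),
            class = "grid_raster")
}

#' @rdname grid_raster
#' @param window a [bbox_window()] the raster should cover.
#' @param fill initial cell value.
#' @return \code{raster_from_window} returns an all-\code{fill} raster whose
#'   extent covers the window (the extent is rounded up to whole cells).
#' @export
raster_from_window <- function(window, cell = 10, fill = 0) {
  nc <- ceiling((window$xmax - window$xmin) / cell)
  nr <- ceiling((window$ymax - window$ymin) / cell)
  grid_raster(matrix(fill, nr, nc), x0 = window$xmin, y0 = window$ymin,
              cell = cell)
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("grid_raster: %d x %d cells of %g m, origin (%g, %g)\n",
              x$nrow, x$ncol, x$cell, x$x0, x$y0))
  cat(sprintf("  values: [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

# Coordinates of every cell centre, in column-major matrix order.
raster_cell_centres <- function(r) {
  list(x = rep(r$x0 + (seq_len(r$ncol) - 0.5) * r$cell, each = r$nrow),
       y = rep(r$y0 + (seq_len(r$nrow) - 0.5) * r$cell, times = r$ncol))
}

raster_extent <- function(r) {
  bbox_window(r$x0, r$x0 + r$ncol * r$cell, r$y0, r$y0 + r$nrow * r$cell)
}

#' Sample a raster at point locations
#'
#' Returns the value of the cell containing each point (nearest-cell rule,
#' no interpolation: covariates are defined as 10 m cell values, and
#' interpolating would invent smoothness the surface does not have). Cells
#' are half-open, \code{[x0 + (j-1) cell, x0 + j cell)}, except that points
#' on the far raster edge are assigned to the last cell.
#'
#' @param raster a [grid_raster()].
#' @param x,y point coordinates in metres (vectors of equal length).
#' @return Numeric vector of cell values.
#' @export
sample_raster <- function(raster, x, y) {
  stopifnot(length(x) == length(y))
  j <- floor((x - raster$x0) / raster$cell) + 1L
  i <- floor((y - raster$y0) / raster$cell) + 1L
  # points exactly on the east/north edge belong to the last cell
  j[x == raster$x0 + raster$ncol * raster$cell] <- raster$ncol
  i[y == raster$y0 + raster$nrow * raster$cell] <- raster$nrow
  bad <- i < 1L | i > raster$nrow | j < 1L | j > raster$ncol
  if (any(bad))
    stop(sprintf("%d point(s) outside raster extent", sum(bad)))
  raster$values[cbind(i, j)]
}

#' Interannual raster correlation
#'
#' Pearson correlation between two aligned rasters over the cells whose
#' centres fall inside \code{mask}, with a Fisher-z 95\% confidence interval.
#' Used to quantify how stable leave-one-year-out habitat-attractiveness
#' surfaces are between years.
#'
#' @param a,b two [grid_raster()]s on identical grids.
#' @param mask optional [bbox_window()]; default uses every cell.
#' @return List with elements \code{r}, \code{ci_low}, \code{ci_high},
#'   \code{n} (number of cells used).
#' @export
raster_correlation <- function(a, b, mask = NULL) {
  if (a$nrow != b$nrow || a$ncol != b$ncol || a$cell != b$cell ||
      a$x0 != b$x0 || a$y0 != b$y0)
    stop("rasters are not on identical grids")
  va <- as.vector(a$values)
  vb <- as.vector(b$values)
  if (!is.null(mask)) {
    cc <- raster_cell_centres(a)
    keep <- inside_window(cc$x, cc$y, mask)
    va <- va[keep]; vb <- vb[keep]
  }
  n <- length(va)
  if (n < 4) stop("fewer than 4 cells in mask")
  r <- stats::cor(va, vb)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  list(r = r, ci_low = tanh(z - 1.96 * se), ci_high = tanh(z + 1.96 * se),
       n = n)
}

#' Read and write ESRI ASCII grid files
#'
#' Plain-text raster exchange format: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of cell
#' values, northernmost row first. Coordinates are planar metres; no CRS
#' handling is attempted.
#'
#' @param path file path.
#' @return \code{read_esri_ascii} returns a [grid_raster()].
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != ncols * nrows)
    stop("ESRI ASCII grid: value count does not match header")
  nodata <- hdr$nodata_value
  if (!is.null(nodata)) vals[vals == nodata] <- NA_real_
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m <- m[nrows:1, , drop = FALSE]  # file stores north first; we store south first
  grid_raster(m, x0 = hdr$xllcorner %||% 0, y0 = hdr$yllcorner %||% 0,
              cell = hdr$cellsize)
}

#' @rdname read_esri_ascii
#' @param raster a [grid_raster()].
#' @export
write_esri_ascii <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", raster$ncol),
    sprintf("nrows %d", raster$nrow),
    sprintf("xllcorner %.10g", raster$x0),
    sprintf("yllcorner %.10g", raster$y0),
    sprintf("cellsize %.10g", raster$cell),
    "NODATA_value -9999"), con)
  m <- raster$values[raster$nrow:1, , drop = FALSE]
  for (i in seq_len(nrow(m)))
    writeLines(paste(format(m[i, ], digits = 10, trim = TRUE),
                     collapse = " "), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
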