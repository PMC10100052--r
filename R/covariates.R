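#' Habitat-attractiveness raster from cumulative nest locations
#'
#' Kernel density estimate of nest density on a regular grid, used as the
#' habitat covariate \emph{hab}. Nest locations accumulated over many years
#' are smoothed with an isotropic Gaussian kernel and evaluated at cell
#' centres on the intensity scale (expected nests per square metre), so the
#' raster integrates approximately to the number of nests whose kernel mass
#' lies inside the window.
#'
#' When a settlement pattern from site s in year y is analysed, nests from
#' that same site and year are excluded from the density estimate
#' (\code{exclude = c(s, y)}) so that the covariate carries no information
#' from the very season being modelled.
#'
#' A small positive floor \code{eps} is added everywhere so that powers
#' \eqn{H^{\alpha}} with negative exponents stay defined; by default
#' \code{eps} is \code{1e-6} times the maximum cell value (or \code{1e-6}
#' when the surface is identically zero).
#'
#' @param nests data frame with columns \code{site}, \code{year}, \code{x},
#'   \code{y} (one row per nest; extra columns ignored).
#' @param window a [bbox_window()].
#' @param exclude optional length-2 vector \code{c(site, year)}: nests with
#'   this site and year label are left out of the estimate.
#' @param bandwidth Gaussian kernel standard deviation in metres.
#' @param cell grid cell size in metres.
#' @param eps positive floor added to every cell; \code{NULL} for the
#'   default described above.
#' @return A [grid_raster()] of strictly positive values.
#' @export
build_attractiveness_raster <- function(nests, window, exclude = NULL,
                                        bandwidth = 50, cell = 10,
                                        eps = NULL) {
  stopifnot(bandwidth > 0)
  r <- raster_from_window(window, cell = cell, fill = 0)
  if (!is.null(exclude)) {
    stopifnot(length(exclude) == 2)
    keep <- !(as.character(nests$site) == as.character(exclude[1]) &
                as.character(nests$year) == as.character(exclude[2]))
    nests <- nests[keep, , drop = FALSE]
  }
  n <- nrow(nests)
  if (n > 0) {
    cc <- raster_cell_centres(r)
    # direct kernel sum: sum over nests of the bivariate Gaussian density
    norm <- 1 / (2 * pi * bandwidth^2)
    v <- numeric(length(cc$x))
    for (k in seq_len(n)) {
      d2 <- (cc$x - nests$x[k])^2 + (cc$y - nests$y[k])^2
      v <- v + norm * exp(-d2 / (2 * bandwidth^2))
    }
    r$values <- matrix(v, r$nrow, r$ncol)
  }
  if (is.null(eps)) {
    m <- max(r$values)
    eps <- if (m > 0) 1e-6 * m else 1e-6
  }
  stopifnot(eps > 0)
  r$values <- r$values + eps
  attr(r, "eps") <- eps
  attr(r, "n_nests") <- n
  r
}

#' Playback-proximity raster
#'
#' Distance-decay covariate for proximity to conspecific song playback
#' stations: each cell takes the value \eqn{e^{-d/200}} where d is the
#' distance in metres from the cell centre to the nearest station midpoint
#' (the midpoint of a station's two speakers is taken as the simulated
#' male's territory centre). Values therefore lie in (0, 1], equal to 1
#' only at a midpoint itself.
#'
#' @param stations data frame of playback stations with columns \code{site},
#'   \code{year}, \code{ax}, \code{ay}, \code{bx}, \code{by},
#'   \code{song_rate_class} (\code{"high"} or \code{"low"}).
#' @param window a [bbox_window()].
#' @param subset \code{"all"} for proximity to any playback
#'   (\emph{prox.all}) or \code{"low_only"} for proximity to low-song-rate
#'   playbacks only (\emph{prox.lc}).
#' @param decay e-folding distance of the decay, metres.
#' @param cell grid cell size in metres.
#' @return A [grid_raster()] with values in (0, 1].
#' @export
build_proximity_raster <- function(stations, window,
                                   subset = c("all", "low_only"),
                                   decay = 200, cell = 10) {
  subset <- match.arg(subset)
  stopifnot(decay > 0)
  if (subset == "low_only")
    stations <- stations[stations$song_rate_class == "low", , drop = FALSE]
  if (nrow(stations) == 0)
    stop("no playback stations left after subsetting")
  mid <- playback_midpoints(stations)
  r <- raster_from_window(window, cell = cell, fill = 0)
  cc <- raster_cell_centres(r)
  dmin <- rep(Inf, length(cc$x))
  for (k in seq_len(nrow(mid))) {
    d <- sqrt((cc$x - mid$x[k])^2 + (cc$y - mid$y[k])^2)
    dmin <- pmin(dmin, d)
  }
  r$values <- matrix(exp(-dmin / decay), r$nrow, r$ncol)
  r
}

#' Midpoints of paired-speaker playback stations
#'
#' @param stations playback-station data frame (see
#'   [build_proximity_raster()]).
#' @return Data frame with columns \code{x}, \code{y},
#'   \code{song_rate_class}, one row per station.
#' @export
playback_midpoints <- function(stations) {
  stopifnot(all(stations$song_rate_class %in% c("high", "low")))
  data.frame(x = (stations$ax + stations$bx) / 2,
             y = (stations$ay + stations$by) / 2,
             song_rate_class = stations$song_rate_class,
             stringsAsFactors = FALSE)
}

#' Read/write the playback-station table
#'
#' CSV schema: \code{site,year,ax,ay,bx,by,song_rate_class}.
#' @param path CSV file path.
#' @export
read_playbacks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "year", "ax", "ay", "bx", "by", "song_rate_class")
  if (!all(need %in% names(df)))
    stop("playbacks CSV must have columns: ", paste(need, collapse = ","))
  df
}
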