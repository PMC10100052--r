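#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data module. The defaults emulate
#' the field study's conditions: five experimental site-year patterns
#' (two sites observed in two years, one in one year) inside ~100 ha
#' windows, cumulative nests accumulated over eleven seasons, paired-speaker
#' playback arrays with high/low song-rate labels at the per-site-year
#' counts of the experiment, settlement intensity
#' \eqn{\lambda(u) = \exp(\beta_0 + \beta_{hab} hab(u) + \beta_{prox}
#' prox(u))} with \eqn{\beta_{hab} = 0.109} and \eqn{\beta_{prox} = 1.773},
#' expected settled-male counts of 22, 21, 1, 1 and 5 (50 in total), and 59
#' settlement choices by 50 females drawn from the conditional-logit model
#' at \eqn{(\alpha_1, \alpha_2) = (0.625, -0.06)}.
#'
#' @param seed integer master seed; every generator forks a deterministic
#'   sub-seed from it, so subsets are reproducible in isolation.
#' @param window_size length-2 numeric, window width and height in metres.
#' @param years integer vector of nest-accumulation years.
#' @param hotspot_count number of Gaussian habitat hotspots per site.
#' @param hotspot_scale hotspot standard deviation, metres.
#' @param hotspot_amplitude length-2 range of hotspot peak heights
#'   (habitat-attractiveness units).
#' @param floor constant habitat floor added everywhere (> 0).
#' @param nests_per_year expected nests per site and year.
#' @param site_years data frame with columns \code{site}, \code{year},
#'   \code{expected_males}, \code{n_high}, \code{n_low} defining the
#'   experimental patterns, their expected settled-male counts and
#'   playback-station counts.
#' @param true_beta named numeric \code{c(beta0, hab, prox)};
#'   \code{beta0 = NA} calibrates the intercept per site-year so the
#'   expected count equals \code{expected_males}.
#' @param true_alpha named numeric \code{c(alpha1, alpha2)}, the
#'   generative attractiveness exponents.
#' @param n_females,n_choices number of choosing females and of choice
#'   events (renesting females choose more than once).
#' @param season character length-2, ISO dates bounding female decisions.
#' @param connectivity_decay e-folding distance for connectivity, metres.
#' @param cell raster cell size, metres.
#' @return A list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(seed = 1,
                              window_size = c(1000, 1000),
                              years = 2010:2020,
                              hotspot_count = 5,
                              hotspot_scale = 120,
                              hotspot_amplitude = c(10, 20),
                              floor = 0.5,
                              nests_per_year = 8,
                              site_years = data.frame(
                                site = c("EW", "EW", "LB", "LB", "HB"),
                                year = c(2017, 2018, 2017, 2018, 2018),
                                expected_males = c(22, 21, 1, 1, 5),
                                n_high = c(4, 6, 3, 2, 2),
                                n_low = c(7, 7, 2, 2, 1)),
                              true_beta = c(beta0 = NA, hab = 0.109,
                                            prox = 1.773),
                              true_alpha = c(alpha1 = 0.625,
                                             alpha2 = -0.06),
                              n_females = 50, n_choices = 59,
                              season = c("2017-04-25", "2017-06-15"),
                              connectivity_decay = 200,
                              cell = 10) {
  stopifnot(length(window_size) == 2, all(window_size > 0),
            hotspot_count >= 0, hotspot_scale > 0, floor > 0,
            nests_per_year >= 0, n_females >= 1, n_choices >= 1,
            connectivity_decay > 0)
  cfg <- list(seed = as.integer(seed), window_size = window_size,
              years = years, hotspot_count = hotspot_count,
              hotspot_scale = hotspot_scale,
              hotspot_amplitude = hotspot_amplitude, floor = floor,
              nests_per_year = nests_per_year, site_years = site_years,
              true_beta = true_beta, true_alpha = true_alpha,
              n_females = n_females, n_choices = n_choices,
              season = as.Date(season),
              connectivity_decay = connectivity_decay, cell = cell)
  cfg$window <- bbox_window(0, window_size[1], 0, window_size[2])
  class(cfg) <- "simulation_config"
  cfg
}

#' Deterministic sub-seed derived from a master seed and a label
#'
#' Forks independent, reproducible random streams for the different
#' generators without coupling them to call order.
#'
#' @param seed master integer seed.
#' @param tag character label of the stream.
#' @return An integer below 2^31.
#' @export
fork_seed <- function(seed, tag) {
  h <- as.double(seed) %% 2147483629
  for (c in utf8ToInt(tag)) h <- (h * 31 + c) %% 2147483629
  as.integer(h)
}

# Run code under a forked seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Latent habitat-attractiveness landscape
#'
#' A strictly positive surface built as a constant floor plus isotropic
#' Gaussian hotspots with random centres and amplitudes — the simplest
#' positive heterogeneous surface consistent with forests whose habitat
#' structure is not homogeneous. Values are on the scale of the habitat
#' covariate (so the study's \eqn{\beta_{hab}} applies directly).
#'
#' @param config a [simulation_config()].
#' @param site site label used to fork the seed (each site gets its own
#'   landscape, constant across years).
#' @return A [grid_raster()] of strictly positive values.
#' @export
gen_landscape <- function(config, site = "S") {
  win <- config$window
  r <- raster_from_window(win, cell = config$cell, fill = config$floor)
  k <- config$hotspot_count
  if (k > 0) {
    with_seed(fork_seed(config$seed, paste0("landscape/", site)), {
      cx <- stats::runif(k, win$xmin, win$xmax)
      cy <- stats::runif(k, win$ymin, win$ymax)
      amp <- stats::runif(k, config$hotspot_amplitude[1],
                          config$hotspot_amplitude[2])
      cc <- raster_cell_centres(r)
      v <- rep(config$floor, length(cc$x))
      for (i in seq_len(k))
        v <- v + amp[i] * exp(-((cc$x - cx[i])^2 + (cc$y - cy[i])^2) /
                                (2 * config$hotspot_scale^2))
      r$values <- matrix(v, r$nrow, r$ncol)
    })
  }
  r
}

# Draw n points with density proportional to a raster's (piecewise
# constant) cell values: cell by weight, then uniform within the cell.
sample_points_from_raster <- function(raster, n) {
  if (n == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  wts <- as.vector(raster$values)
  idx <- sample.int(length(wts), n, replace = TRUE, prob = wts)
  i <- (idx - 1L) %% raster$nrow + 1L
  j <- (idx - 1L) %/% raster$nrow + 1L
  data.frame(
    x = raster$x0 + (j - 1L + stats::runif(n)) * raster$cell,
    y = raster$y0 + (i - 1L + stats::runif(n)) * raster$cell)
}

#' Cumulative nest records over many seasons
#'
#' Per year the nest count is Poisson(\code{nests_per_year}) and locations
#' are drawn with density proportional to the latent surface, so attractive
#' habitat accumulates nests across years. Each record carries a clutch
#' size (5-7 eggs) and a clutch completion date, from which the
#' preprocessing rules can back-date nest initiation.
#'
#' @param config a [simulation_config()].
#' @param surface positive [grid_raster()], normally from
#'   [gen_landscape()].
#' @param site site label.
#' @return Data frame with columns \code{site}, \code{year}, \code{x},
#'   \code{y}, \code{female_id}, \code{clutch_size},
#'   \code{clutch_completion} (Date).
#' @export
gen_nests <- function(config, surface, site = "S") {
  stopifnot(all(surface$values > 0))
  with_seed(fork_seed(config$seed, paste0("nests/", site)), {
    out <- lapply(config$years, function(yr) {
      n <- stats::rpois(1, config$nests_per_year)
      if (n == 0) return(NULL)
      pts <- sample_points_from_raster(surface, n)
      data.frame(site = site, year = yr, x = pts$x, y = pts$y,
                 female_id = sprintf("%s%d-f%02d", site, yr, seq_len(n)),
                 clutch_size = sample(5:7, n, replace = TRUE),
                 clutch_completion = as.Date(sprintf("%d-05-10", yr)) +
                   sample.int(40, n, replace = TRUE) - 1L,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
      out <- data.frame(site = character(0), year = integer(0),
                        x = numeric(0), y = numeric(0),
                        female_id = character(0), clutch_size = integer(0),
                        clutch_completion = as.Date(character(0)))
    out
  })
}

#' Playback-station array for one site-year
#'
#' Places \code{n_high + n_low} paired-speaker stations at random positions
#' at least 150 m apart (and 100 m inside the window edge), with speakers
#' 100 m apart around each station midpoint and song-rate classes assigned
#' to stations at random.
#'
#' @param config a [simulation_config()].
#' @param site,year labels (also fork the seed).
#' @param n_high,n_low station counts per class.
#' @return Playback-station data frame (see [build_proximity_raster()]).
#' @export
gen_playbacks <- function(config, site = "S", year = NA, n_high = 4,
                          n_low = 7) {
  n <- n_high + n_low
  win <- config$window
  with_seed(fork_seed(config$seed, sprintf("playbacks/%s/%s", site, year)), {
    mx <- my <- numeric(0)
    tries <- 0
    while (length(mx) < n && tries < 10000) {
      tries <- tries + 1
      px <- stats::runif(1, win$xmin + 100, win$xmax - 100)
      py <- stats::runif(1, win$ymin + 100, win$ymax - 100)
      if (length(mx) == 0 || min((mx - px)^2 + (my - py)^2) >= 150^2) {
        mx <- c(mx, px); my <- c(my, py)
      }
    }
    if (length(mx) < n)
      stop("could not place playback stations 150 m apart in this window")
    theta <- stats::runif(n, 0, 2 * pi)
    cls <- sample(c(rep("high", n_high), rep("low", n_low)))
    data.frame(site = site, year = year,
               ax = mx + 50 * cos(theta), ay = my + 50 * sin(theta),
               bx = mx - 50 * cos(theta), by = my - 50 * sin(theta),
               song_rate_class = cls, stringsAsFactors = FALSE)
  })
}

#' Calibrate the settlement-model intercept to an expected count
#'
#' Solves \eqn{\int_W \exp(\beta_0 + \beta_{hab} hab + \beta_{prox} prox)
#' du = } \code{target} for \eqn{\beta_0} on the covariate grid.
#'
#' @param target expected number of settled males.
#' @param hab habitat [grid_raster()].
#' @param prox playback-proximity [grid_raster()] or \code{NULL}.
#' @param beta_hab,beta_prox loglinear coefficients.
#' @return The intercept \eqn{\beta_0}.
#' @export
calibrate_beta0 <- function(target, hab, prox = NULL, beta_hab = 0,
                            beta_prox = 0) {
  stopifnot(target > 0)
  eta <- beta_hab * as.vector(hab$values)
  if (!is.null(prox)) eta <- eta + beta_prox * as.vector(prox$values)
  log(target) - log(sum(exp(eta)) * hab$cell^2)
}

#' Male settlement pattern from the loglinear intensity
#'
#' Samples an inhomogeneous Poisson point process with intensity
#' \eqn{\lambda(u) = \exp(\beta_0 + \beta_{hab} hab(u) + \beta_{prox}
#' prox(u))} by thinning a dominating homogeneous process: candidate points
#' are generated at the cell-wise maximum intensity (exact for piecewise
#' constant covariates, valid for coefficients of any sign) and retained
#' with probability \eqn{\lambda(u)/\lambda_{max}}.
#'
#' @param config a [simulation_config()]; \code{true_beta} supplies the
#'   coefficients, with \code{beta0 = NA} calibrated via
#'   [calibrate_beta0()] to \code{expected_males}.
#' @param hab habitat [grid_raster()].
#' @param prox proximity [grid_raster()] or \code{NULL} (no playback term).
#' @param site,year labels.
#' @param expected_males target expected count used when \code{beta0} is
#'   \code{NA}.
#' @return A [point_pattern()].
#' @export
gen_male_pattern <- function(config, hab, prox = NULL, site = "S",
                             year = NA, expected_males = 10) {
  b <- config$true_beta
  b0 <- b[1]
  if (is.na(b0))
    b0 <- calibrate_beta0(expected_males, hab, prox, b[2], b[3])
  eta_cells <- b0 + b[2] * as.vector(hab$values)
  if (!is.null(prox)) eta_cells <- eta_cells + b[3] * as.vector(prox$values)
  lmax <- exp(max(eta_cells))
  if (!is.finite(lmax)) stop("dominating intensity is not finite")
  win <- config$window
  with_seed(fork_seed(config$seed, sprintf("males/%s/%s", site, year)), {
    n_dom <- stats::rpois(1, lmax * window_area(win))
    x <- stats::runif(n_dom, win$xmin, win$xmax)
    y <- stats::runif(n_dom, win$ymin, win$ymax)
    eta <- b0 + b[2] * sample_raster(hab, x, y)
    if (!is.null(prox)) eta <- eta + b[3] * sample_raster(prox, x, y)
    keep <- stats::runif(n_dom) < exp(eta) / lmax
    point_pattern(x[keep], y[keep], win, site = site, year = year,
                  male_id = sprintf("%s%s-m%03d", site,
                                    ifelse(is.na(year), "", year),
                                    seq_len(sum(keep))))
  })
}

#' Female choice events from the conditional-logit model
#'
#' For each simulated choice, the candidate set is the snapshot of all
#' settled males in the site-year; each candidate's habitat value H is the
#' attractiveness raster at his location and his connectivity C includes
#' playback midpoints as competitors. The chosen male is drawn with
#' probability \eqn{p_i = H_i^{\alpha_1} C_i^{\alpha_2} / \sum_j
#' H_j^{\alpha_1} C_j^{\alpha_2}} at the configured true exponents, and
#' each female's decision date is uniform over the season.
#'
#' @param config a [simulation_config()].
#' @param males a [point_pattern()] of settled males (at least one).
#' @param hab habitat [grid_raster()] supplying H.
#' @param playbacks playback-station data frame for the site-year, or
#'   \code{NULL}.
#' @param n_events number of choices to draw.
#' @param female_id optional character vector of female ids (recycled
#'   ids mean repeat choices by renesting females).
#' @return List of [choice_event()]s (class \code{"choice_events"}).
#' @export
gen_choice_events <- function(config, males, hab, playbacks = NULL,
                              n_events = config$n_choices,
                              female_id = NULL) {
  if (males$n < 1) stop("cannot simulate choices with no males present")
  a <- config$true_alpha
  H <- sample_raster(hab, males$x, males$y)
  mid <- if (!is.null(playbacks)) playback_midpoints(playbacks) else NULL
  C <- compute_connectivities(data.frame(x = males$x, y = males$y), mid,
                              include_playbacks = TRUE,
                              decay = config$connectivity_decay)
  cand <- data.frame(male_id = males$male_id, x = males$x, y = males$y,
                     H = H, C = C, stringsAsFactors = FALSE)
  if (is.null(female_id))
    female_id <- sprintf("f%04d", seq_len(n_events))
  with_seed(fork_seed(config$seed,
                      sprintf("choices/%s/%s", males$site, males$year)), {
    dates <- config$season[1] +
      sample.int(as.integer(diff(config$season)) + 1L, n_events,
                 replace = TRUE) - 1L
    # the candidate snapshot (and hence p) is shared by the scene's events;
    # a single-candidate scene picks its male with certainty
    proto <- choice_event(cand, 1L)  # validates H and C once
    p <- choice_probabilities(proto, a[1], a[2])
    ch <- sample.int(nrow(cand), n_events, replace = TRUE, prob = p)
    events <- lapply(seq_len(n_events), function(i) {
      e <- proto
      e$chosen <- ch[i]
      e$female_id <- female_id[i]
      e$site <- males$site
      e$year <- males$year
      e$decision_date <- dates[i]
      e
    })
    structure(events, class = "choice_events")
  })
}

#' Generate the per-site-year scenes of a synthetic study
#'
#' Builds, per site, a latent landscape, and per site-year a playback
#' array, its proximity raster and a settled-male pattern from the
#' loglinear intensity.
#'
#' @param config a [simulation_config()].
#' @return Named list of scenes (keyed \code{site-year}), each with
#'   elements \code{site}, \code{year}, \code{hab} (the site landscape),
#'   \code{playbacks}, \code{prox} and \code{males}.
#' @export
gen_study_scenes <- function(config = simulation_config()) {
  sy <- config$site_years
  sites <- unique(sy$site)
  landscapes <- lapply(sites, function(s) gen_landscape(config, s))
  names(landscapes) <- sites
  scenes <- vector("list", nrow(sy))
  for (i in seq_len(nrow(sy))) {
    s <- sy$site[i]; yr <- sy$year[i]
    pb <- gen_playbacks(config, s, yr, sy$n_high[i], sy$n_low[i])
    prox <- build_proximity_raster(pb, config$window, "all",
                                   cell = config$cell)
    males <- gen_male_pattern(config, landscapes[[s]], prox, s, yr,
                              expected_males = sy$expected_males[i])
    scenes[[i]] <- list(site = s, year = yr, hab = landscapes[[s]],
                        playbacks = pb, prox = prox, males = males)
  }
  names(scenes) <- sprintf("%s-%s", sy$site, sy$year)
  attr(scenes, "landscapes") <- landscapes
  scenes
}

#' Draw the study's female choice events across scenes
#'
#' Allocates \code{n_events} choices across the site-year scenes in
#' proportion to their settled-male counts (largest-remainder rounding;
#' scenes without males receive none) and draws each choice from the
#' conditional-logit model at the configured true exponents. Renesting
#' females are assigned where there are more choices than females.
#'
#' @param config a [simulation_config()].
#' @param scenes output of [gen_study_scenes()].
#' @param n_events total number of choices.
#' @return List of [choice_event()]s (class \code{"choice_events"}).
#' @export
gen_study_choices <- function(config, scenes,
                              n_events = config$n_choices) {
  counts <- vapply(scenes, function(sc) sc$males$n, integer(1))
  alloc <- allocate_proportional(n_events, counts)
  fem <- assign_females(n_events, config$n_females)
  events <- list()
  off <- 0
  for (i in seq_along(scenes)) {
    if (alloc[i] == 0) next
    sc <- scenes[[i]]
    ev <- gen_choice_events(config, sc$males, sc$hab, sc$playbacks,
                            n_events = alloc[i],
                            female_id = fem[off + seq_len(alloc[i])])
    events <- c(events, ev)
    off <- off + alloc[i]
  }
  structure(events, class = "choice_events")
}

#' Simulate the full synthetic study
#'
#' Combines [gen_study_scenes()], [gen_nests()] and
#' [gen_study_choices()], and additionally fabricates raw
#' territory-observation tables whose preprocessing (tenure filter, 150 m
#' territory clustering) recovers the settled males, plus transient
#' (< 5-day) males that the filter must drop.
#'
#' @param config a [simulation_config()].
#' @return List with elements \code{config}, \code{landscapes} (per site),
#'   \code{nests} (one table), \code{scenes} (per site-year: hab and prox
#'   rasters, playbacks, males), \code{events} (all choice events pooled),
#'   \code{territories} (raw observation table).
#' @export
simulate_study <- function(config = simulation_config()) {
  scenes <- gen_study_scenes(config)
  landscapes <- attr(scenes, "landscapes")
  nests <- do.call(rbind, lapply(names(landscapes), function(s)
    gen_nests(config, landscapes[[s]], s)))
  events <- gen_study_choices(config, scenes)
  territories <- do.call(rbind, lapply(scenes, function(sc)
    gen_territories(config, sc$males)))
  rownames(territories) <- NULL
  list(config = config, landscapes = landscapes, nests = nests,
       scenes = scenes, events = events, territories = territories)
}

# Largest-remainder allocation of n items proportional to weights, with
# zero weight getting zero items.
allocate_proportional <- function(n, weights) {
  if (sum(weights) == 0) stop("no capacity to allocate choices to")
  q <- n * weights / sum(weights)
  a <- floor(q)
  rem <- n - sum(a)
  if (rem > 0) {
    o <- order(q - a, decreasing = TRUE)
    a[o[seq_len(rem)]] <- a[o[seq_len(rem)]] + 1
  }
  as.integer(a)
}

# Female ids for n_choices events by n_females females: the first
# (n_choices - n_females) females renest and choose twice.
assign_females <- function(n_choices, n_females) {
  base <- sprintf("f%03d", seq_len(min(n_choices, n_females)))
  extra <- n_choices - length(base)
  if (extra > 0) base <- c(base, base[seq_len(extra)])
  base
}

# Raw territory observations consistent with a settled-male pattern:
# 1-3 singing locations jittered < 50 m around each male's centre over a
# >= 5-day tenure; ~15% of males get a second, shorter-tenure territory
# >= 150 m away (polyterritoriality); plus transient males present < 5
# days that preprocessing must exclude.
gen_territories <- function(config, males) {
  win <- config$window
  with_seed(fork_seed(config$seed,
                      sprintf("territories/%s/%s", males$site, males$year)), {
    rows <- list()
    s0 <- config$season[1] - 10
    for (i in seq_len(males$n)) {
      arr <- s0 + sample.int(25, 1)
      ten <- 5 + stats::rpois(1, 15)
      nob <- sample.int(3, 1)
      ang <- stats::runif(nob, 0, 2 * pi)
      rad <- stats::runif(nob, 0, 49)
      ox <- pmin(pmax(males$x[i] + rad * cos(ang), win$xmin), win$xmax)
      oy <- pmin(pmax(males$y[i] + rad * sin(ang), win$ymin), win$ymax)
      rows[[length(rows) + 1]] <- data.frame(
        male_id = males$male_id[i], site = males$site, year = males$year,
        x = ox, y = oy, first_seen = rep(arr, nob),
        last_seen = rep(arr + ten - 1L, nob),
        stringsAsFactors = FALSE)
      if (stats::runif(1) < 0.15) {  # secondary territory, strictly shorter
        ang2 <- stats::runif(1, 0, 2 * pi)
        sx <- males$x[i] + 250 * cos(ang2)
        sy_ <- males$y[i] + 250 * sin(ang2)
        if (inside_window(sx, sy_, win)) {
          d2 <- arr + ten + sample.int(5, 1)
          rows[[length(rows) + 1]] <- data.frame(
            male_id = males$male_id[i], site = males$site,
            year = males$year, x = sx, y = sy_,
            first_seen = d2, last_seen = d2 + max(0, ten - 3),
            stringsAsFactors = FALSE)
        }
      }
    }
    n_trans <- stats::rpois(1, 0.2 * max(males$n, 1))
    for (t in seq_len(n_trans)) {
      arr <- s0 + sample.int(40, 1)
      rows[[length(rows) + 1]] <- data.frame(
        male_id = sprintf("%s%s-t%02d", males$site,
                          ifelse(is.na(males$year), "", males$year), t),
        site = males$site, year = males$year,
        x = stats::runif(1, win$xmin, win$xmax),
        y = stats::runif(1, win$ymin, win$ymax),
        first_seen = arr, last_seen = arr + sample.int(4, 1) - 1L,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
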