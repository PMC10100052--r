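#' Cluster a male's singing locations into territories
#'
#' Territories are defined by spatial separation: singing locations less
#' than \code{threshold} metres apart belong to the same territory
#' (single-linkage: any chain of sub-threshold links joins locations into
#' one cluster), while locations \code{threshold} or more metres apart are
#' distinct territories. The territory centre is the centroid of its
#' member locations and its tenure the inclusive day span of their dates.
#'
#' @param observations data frame of one or more males' singing-location
#'   records: columns \code{male_id}, \code{site}, \code{year}, \code{x},
#'   \code{y}, \code{first_seen}, \code{last_seen} (Dates or ISO strings).
#' @param threshold separation defining distinct territories, metres.
#' @return Data frame with one row per male-site-year territory: columns
#'   \code{male_id}, \code{site}, \code{year}, \code{territory}, \code{x},
#'   \code{y} (centroid), \code{first_seen}, \code{last_seen},
#'   \code{tenure} (days, inclusive), \code{n_obs}.
#' @export
cluster_territories <- function(observations, threshold = 150) {
  obs <- normalize_observations(observations)
  key <- interaction(obs$male_id, obs$site, obs$year, drop = TRUE)
  out <- lapply(split(obs, key), function(o) {
    lab <- single_linkage_labels(o$x, o$y, threshold)
    terr <- lapply(sort(unique(lab)), function(l) {
      m <- o[lab == l, , drop = FALSE]
      data.frame(male_id = m$male_id[1], site = m$site[1],
                 year = m$year[1], territory = l,
                 x = mean(m$x), y = mean(m$y),
                 first_seen = min(m$first_seen),
                 last_seen = max(m$last_seen),
                 n_obs = nrow(m), stringsAsFactors = FALSE)
    })
    do.call(rbind, terr)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$tenure <- as.integer(out$last_seen - out$first_seen) + 1L
  out
}

# Union-find single linkage: components of the graph linking pairs with
# distance strictly below the threshold (>= threshold separates).
single_linkage_labels <- function(x, y, threshold) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if ((x[i] - x[j])^2 + (y[i] - y[j])^2 < threshold^2) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

normalize_observations <- function(observations) {
  need <- c("male_id", "site", "year", "x", "y", "first_seen", "last_seen")
  if (!all(need %in% names(observations)))
    stop("observations need columns: ", paste(need, collapse = ", "))
  obs <- observations
  obs$first_seen <- as.Date(obs$first_seen)
  obs$last_seen <- as.Date(obs$last_seen)
  if (any(obs$last_seen < obs$first_seen))
    stop("last_seen before first_seen in observations")
  obs
}

#' Reduce observations to settled males, one territory each
#'
#' Applies the settlement rules: a male counts as settled in a site-year
#' only if his presence there (first to last observation, inclusive) spans
#' at least \code{min_days} days. For settled males holding several
#' territories (singing locations \eqn{\ge} 150 m apart), the territory
#' with the longest tenure is kept; ties go to the chronologically first
#' territory. The result has exactly one location per male per site-year,
#' the independence the point patterns require.
#'
#' @inheritParams cluster_territories
#' @param min_days minimum site presence in days.
#' @return Data frame of settled males: \code{male_id}, \code{site},
#'   \code{year}, \code{x}, \code{y}, \code{tenure}, \code{first_seen},
#'   \code{last_seen}.
#' @export
filter_settled_males <- function(observations, min_days = 5,
                                 threshold = 150) {
  obs <- normalize_observations(observations)
  key <- interaction(obs$male_id, obs$site, obs$year, drop = TRUE)
  presence <- vapply(split(obs, key), function(o)
    as.integer(max(o$last_seen) - min(o$first_seen)) + 1L, integer(1))
  settled_keys <- names(presence)[presence >= min_days]
  obs <- obs[key %in% settled_keys, , drop = FALSE]
  if (nrow(obs) == 0)
    return(data.frame(male_id = character(0), site = character(0),
                      year = integer(0), x = numeric(0), y = numeric(0),
                      tenure = integer(0),
                      first_seen = as.Date(character(0)),
                      last_seen = as.Date(character(0))))
  terr <- cluster_territories(obs, threshold)
  key2 <- interaction(terr$male_id, terr$site, terr$year, drop = TRUE)
  pick <- lapply(split(terr, key2), function(tt) {
    tt <- tt[order(-tt$tenure, tt$first_seen), , drop = FALSE]
    tt[1, , drop = FALSE]
  })
  out <- do.call(rbind, pick)
  rownames(out) <- NULL
  out[, c("male_id", "site", "year", "x", "y", "tenure",
          "first_seen", "last_seen")]
}

#' Settled males as per-site-year point patterns
#'
#' @param settled output of [filter_settled_males()].
#' @param windows a single [bbox_window()] used for every site, or a named
#'   list of windows keyed by site.
#' @return Named list of [point_pattern()]s, keyed \code{site-year}.
#' @export
settled_to_patterns <- function(settled, windows) {
  key <- interaction(settled$site, settled$year, drop = TRUE, sep = "-")
  out <- lapply(split(settled, key), function(s) {
    win <- if (inherits(windows, "bbox_window")) windows
           else windows[[as.character(s$site[1])]]
    point_pattern(s$x, s$y, win, site = s$site[1], year = s$year[1],
                  male_id = s$male_id)
  })
  out
}

#' Back-date nest and clutch initiation from clutch completion
#'
#' Applies the nest-timing rules: one egg is laid per day, so clutch
#' initiation is clutch completion minus (clutch size - 1) days; nest
#' initiation (the female's settlement decision date) is 7 days before
#' clutch initiation; incubation runs 14 days from clutch completion.
#'
#' @param nests data frame with columns \code{clutch_completion} (Date or
#'   ISO string) and \code{clutch_size} (\eqn{\ge} 1).
#' @return The input with added Date columns \code{clutch_initiation},
#'   \code{nest_initiation} and \code{incubation_end}.
#' @export
estimate_nest_initiation <- function(nests) {
  if (any(is.na(nests$clutch_size)) || any(nests$clutch_size < 1))
    stop("clutch_size must be >= 1")
  cc <- as.Date(nests$clutch_completion)
  nests$clutch_completion <- cc
  nests$clutch_initiation <- cc - (nests$clutch_size - 1)
  nests$nest_initiation <- nests$clutch_initiation - 7
  nests$incubation_end <- cc + 14
  nests
}

#' Build female choice events from nests and male survey snapshots
#'
#' For each nest record, selects the survey snapshot of the female's site
#' closest in time to her nest initiation date (ties resolved towards the
#' earlier survey), takes every male present in that snapshot as a
#' candidate — already-paired males included — and attaches each
#' candidate's habitat value H (attractiveness raster at his location) and
#' connectivity C (optionally counting playback midpoints as competitors).
#' The chosen candidate is the male named in the nest's \code{mate_id}
#' column when present; otherwise the male nearest the nest is taken as
#' the mate.
#'
#' @param nests nest records carrying \code{site}, \code{year}, \code{x},
#'   \code{y}, \code{female_id}, and either \code{nest_initiation} or the
#'   columns needed by [estimate_nest_initiation()]; optional
#'   \code{mate_id}.
#' @param surveys dated male-location snapshots: columns \code{male_id},
#'   \code{site}, \code{year}, \code{x}, \code{y}, \code{survey_date}.
#' @param hab a [grid_raster()] of habitat attractiveness, or a named list
#'   of such rasters keyed by site.
#' @param playbacks playback-station table (may be \code{NULL}); only
#'   stations matching the event's site and year contribute.
#' @param include_playbacks whether playback midpoints count as
#'   competitors in C.
#' @param decay connectivity e-folding distance, metres.
#' @return List of [choice_event()]s (class \code{"choice_events"}).
#' @export
build_choice_events <- function(nests, surveys, hab, playbacks = NULL,
                                include_playbacks = TRUE, decay = 200) {
  if (!"nest_initiation" %in% names(nests))
    nests <- estimate_nest_initiation(nests)
  surveys$survey_date <- as.Date(surveys$survey_date)
  events <- vector("list", nrow(nests))
  for (i in seq_len(nrow(nests))) {
    nest <- nests[i, ]
    sv <- surveys[surveys$site == nest$site & surveys$year == nest$year, ,
                  drop = FALSE]
    if (nrow(sv) == 0)
      stop("no survey snapshots for site ", nest$site, " year ", nest$year)
    gap <- abs(as.integer(sv$survey_date - as.Date(nest$nest_initiation)))
    # nearest snapshot; ties towards the earlier survey
    best <- sv$survey_date[order(gap, sv$survey_date)][1]
    snap <- sv[sv$survey_date == best, , drop = FALSE]
    hr <- if (inherits(hab, "grid_raster")) hab
          else hab[[as.character(nest$site)]]
    H <- sample_raster(hr, snap$x, snap$y)
    mid <- NULL
    if (!is.null(playbacks)) {
      pb <- playbacks[playbacks$site == nest$site &
                        playbacks$year == nest$year, , drop = FALSE]
      if (nrow(pb) > 0) mid <- playback_midpoints(pb)
    }
    C <- compute_connectivities(data.frame(x = snap$x, y = snap$y), mid,
                                include_playbacks = include_playbacks,
                                decay = decay)
    cand <- data.frame(male_id = snap$male_id, x = snap$x, y = snap$y,
                       H = H, C = C, stringsAsFactors = FALSE)
    chosen <- if ("mate_id" %in% names(nests) && !is.na(nest$mate_id)) {
      match(nest$mate_id, cand$male_id)
    } else {
      which.min((cand$x - nest$x)^2 + (cand$y - nest$y)^2)
    }
    if (is.na(chosen))
      stop("chosen mate ", nest$mate_id, " absent from snapshot")
    ev <- choice_event(cand, chosen, female_id = nest$female_id,
                       site = nest$site,
                       decision_date = as.Date(nest$nest_initiation))
    ev$year <- nest$year
    events[[i]] <- ev
  }
  structure(events, class = "choice_events")
}

#' Weekly male-presence snapshots from territory observations
#'
#' Convenience for building the survey table the choice-event constructor
#' needs: at each survey date, every settled male whose observed presence
#' interval covers that date appears at his territory centre.
#'
#' @param settled output of [filter_settled_males()].
#' @param dates vector of survey Dates.
#' @return Survey data frame (see [build_choice_events()]).
#' @export
snapshots_from_settled <- function(settled, dates) {
  dates <- as.Date(dates)
  out <- lapply(dates, function(d) {
    pres <- settled[settled$first_seen <= d & settled$last_seen >= d, ,
                    drop = FALSE]
    if (nrow(pres) == 0) return(NULL)
    data.frame(male_id = pres$male_id, site = pres$site, year = pres$year,
               x = pres$x, y = pres$y, survey_date = d,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read and write choice events as a flat CSV
#'
#' Schema: one row per candidate male per event, columns
#' \code{female_id,site,year,decision_date,candidate_male_id,x,y,H,C,chosen}
#' with \code{chosen} 0/1 and exactly one 1 per event. Events are keyed by
#' \code{female_id + decision_date + site + year}.
#'
#' @param events list of [choice_event()]s.
#' @param path CSV path.
#' @export
write_choices_csv <- function(events, path) {
  rows <- lapply(seq_along(events), function(i) {
    e <- events[[i]]
    data.frame(event = i, female_id = e$female_id, site = e$site,
               year = if (is.null(e$year)) NA else e$year,
               decision_date = as.character(e$decision_date),
               candidate_male_id = e$candidates$male_id,
               x = e$candidates$x, y = e$candidates$y,
               H = e$candidates$H, C = e$candidates$C,
               chosen = as.integer(seq_len(nrow(e$candidates)) == e$chosen),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_choices_csv
#' @export
read_choices_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"event" %in% names(df))
    df$event <- cumsum(!duplicated(df[, c("female_id", "decision_date",
                                          "site", "year")]))
  events <- lapply(split(df, df$event), function(g) {
    ev <- choice_event(
      data.frame(male_id = g$candidate_male_id, x = g$x, y = g$y,
                 H = g$H, C = g$C, stringsAsFactors = FALSE),
      chosen = which(g$chosen == 1),
      female_id = g$female_id[1], site = g$site[1],
      decision_date = as.Date(g$decision_date[1]))
    ev$year <- g$year[1]
    ev
  })
  structure(unname(events), class = "choice_events")
}

#' Recompute event connectivities including or excluding playbacks
#'
#' The include- and exclude-playback analysis variants differ only through
#' the C values: the candidate sets are identical. This helper recomputes C
#' for every event from the candidates' coordinates.
#'
#' @param events list of [choice_event()]s carrying \code{site} and
#'   \code{year}.
#' @param playbacks playback-station table (or \code{NULL}).
#' @inheritParams build_choice_events
#' @return The events with updated C columns.
#' @export
set_event_connectivity <- function(events, playbacks,
                                   include_playbacks = TRUE, decay = 200) {
  out <- lapply(events, function(e) {
    mid <- NULL
    if (include_playbacks && !is.null(playbacks)) {
      pb <- playbacks[playbacks$site == e$site &
                        playbacks$year == e$year, , drop = FALSE]
      if (nrow(pb) > 0) mid <- playback_midpoints(pb)
    }
    e$candidates$C <- compute_connectivities(
      e$candidates[, c("x", "y")], mid,
      include_playbacks = include_playbacks, decay = decay)
    e
  })
  structure(out, class = "choice_events")
}
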