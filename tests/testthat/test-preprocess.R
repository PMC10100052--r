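obs_row <- function(male = "m1", site = "EW", year = 2017, x = 0, y = 0,
                    first = "2017-05-01", last = first) {
  data.frame(male_id = male, site = site, year = year, x = x, y = y,
             first_seen = first, last_seen = last,
             stringsAsFactors = FALSE)
}

test_that("territory clustering respects the 150 m separation definition", {
  # two singing locations 120 m apart: one territory
  obs <- rbind(obs_row(x = 0), obs_row(x = 120, first = "2017-05-04"))
  t1 <- cluster_territories(obs)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$x, 60)  # centroid
  expect_equal(t1$tenure, 4L)

  # exactly 150 m apart: >= 150 means distinct territories
  obs <- rbind(obs_row(x = 0), obs_row(x = 150))
  expect_equal(nrow(cluster_territories(obs)), 2)

  # single location: one territory at that point
  t3 <- cluster_territories(obs_row(x = 42, y = 17))
  expect_equal(nrow(t3), 1)
  expect_equal(c(t3$x, t3$y), c(42, 17))

  # single linkage chains: 0 -- 140 -- 280 all join despite 280 > 150
  obs <- rbind(obs_row(x = 0), obs_row(x = 140), obs_row(x = 280))
  expect_equal(nrow(cluster_territories(obs)), 1)
})

test_that("settlement requires at least five days of site presence", {
  four <- obs_row(first = "2017-05-01", last = "2017-05-04")
  five <- obs_row(male = "m2", first = "2017-05-01", last = "2017-05-05")
  out <- filter_settled_males(rbind(four, five))
  expect_equal(out$male_id, "m2")
  expect_equal(out$tenure, 5L)
})

test_that("multi-territory males keep the longest-tenure territory, ties to the first", {
  # tenures 10 d at x=0 and 7 d at x=400: keep x=0
  obs <- rbind(obs_row(x = 0, first = "2017-05-01", last = "2017-05-10"),
               obs_row(x = 400, first = "2017-05-12", last = "2017-05-18"))
  out <- filter_settled_males(obs)
  expect_equal(nrow(out), 1)
  expect_equal(out$x, 0)
  # equal tenures: chronologically first territory wins
  obs <- rbind(obs_row(x = 400, first = "2017-05-12", last = "2017-05-18"),
               obs_row(x = 0, first = "2017-05-01", last = "2017-05-07"))
  expect_equal(filter_settled_males(obs)$x, 0)
})

test_that("preprocessing yields one settled male per site-year and drops transients", {
  sim <- simulate_study(simulation_config(seed = 21))
  settled <- filter_settled_males(sim$territories)
  key <- paste(settled$male_id, settled$site, settled$year)
  expect_equal(anyDuplicated(key), 0)
  expect_true(all(settled$tenure >= 5))
  # transients (ids containing "-t") were generated with < 5-day presence
  expect_false(any(grepl("-t", settled$male_id)))
  # every generated settled male survives the filter with his centre
  for (sc in sim$scenes) {
    got <- settled[settled$site == sc$site & settled$year == sc$year, ]
    expect_setequal(got$male_id, sc$males$male_id)
    if (sc$males$n == 0) next
    m <- match(sc$males$male_id, got$male_id)
    expect_lt(max(abs(got$x[m] - sc$males$x)), 50)
  }
  pats <- settled_to_patterns(settled, sim$config$window)
  n_occupied <- sum(vapply(sim$scenes, function(sc) sc$males$n, integer(1)) > 0)
  expect_equal(length(pats), n_occupied)
})

test_that("nest and clutch initiation follow the laying and building rules", {
  n <- estimate_nest_initiation(
    data.frame(clutch_completion = "2017-05-20", clutch_size = 6))
  expect_equal(n$clutch_initiation, as.Date("2017-05-15"))
  expect_equal(n$nest_initiation, as.Date("2017-05-08"))
  expect_equal(n$incubation_end, as.Date("2017-06-03"))
  # clutch of 1: initiation is completion day
  n1 <- estimate_nest_initiation(
    data.frame(clutch_completion = "2017-05-20", clutch_size = 1))
  expect_equal(n1$clutch_initiation, as.Date("2017-05-20"))
  expect_error(estimate_nest_initiation(
    data.frame(clutch_completion = "2017-05-20", clutch_size = 0)),
    "clutch_size")
})

test_that("choice events use the snapshot nearest in time, ties to the earlier survey", {
  win <- bbox_window(0, 500, 0, 500)
  hab <- const_raster(win, 2)
  surveys <- rbind(
    data.frame(male_id = c("a", "b"), site = "EW", year = 2017,
               x = c(100, 300), y = c(100, 300),
               survey_date = "2017-05-06"),
    data.frame(male_id = c("a", "b", "c"), site = "EW", year = 2017,
               x = c(100, 300, 200), y = c(100, 300, 200),
               survey_date = "2017-05-12"))
  nest <- data.frame(site = "EW", year = 2017, x = 110, y = 110,
                     female_id = "f1", nest_initiation = "2017-05-08")
  ev <- build_choice_events(nest, surveys, hab)
  # May 6 is 2 days away, May 12 is 4: the earlier snapshot wins, male c absent
  expect_equal(nrow(ev[[1]]$candidates), 2)
  expect_setequal(ev[[1]]$candidates$male_id, c("a", "b"))
  # equidistant snapshots: ties resolved towards the earlier one
  nest2 <- data.frame(site = "EW", year = 2017, x = 110, y = 110,
                      female_id = "f2", nest_initiation = "2017-05-09")
  ev2 <- build_choice_events(nest2, surveys, hab)
  expect_equal(nrow(ev2[[1]]$candidates), 2)
  # the nearest male is taken as the mate when no mate_id is given
  expect_equal(ev2[[1]]$candidates$male_id[ev2[[1]]$chosen], "a")
  # an explicit mate_id overrides proximity (paired males stay candidates)
  nest3 <- cbind(nest, mate_id = "b")
  ev3 <- build_choice_events(nest3, surveys, hab)
  expect_equal(ev3[[1]]$candidates$male_id[ev3[[1]]$chosen], "b")
  expect_error(build_choice_events(
    data.frame(site = "XX", year = 2017, x = 0, y = 0, female_id = "f",
               nest_initiation = "2017-05-08"), surveys, hab),
    "no survey")
})

test_that("playbacks contribute to connectivity but never to the candidate set", {
  win <- bbox_window(0, 500, 0, 500)
  hab <- const_raster(win, 2)
  surveys <- data.frame(male_id = c("a", "b"), site = "EW", year = 2017,
                        x = c(100, 300), y = c(100, 100),
                        survey_date = "2017-05-06")
  pb <- data.frame(site = "EW", year = 2017, ax = 150, ay = 150, bx = 250,
                   by = 150, song_rate_class = "low")
  nest <- data.frame(site = "EW", year = 2017, x = 110, y = 110,
                     female_id = "f1", nest_initiation = "2017-05-08")
  with_pb <- build_choice_events(nest, surveys, hab, pb,
                                 include_playbacks = TRUE)
  without <- build_choice_events(nest, surveys, hab, pb,
                                 include_playbacks = FALSE)
  expect_setequal(with_pb[[1]]$candidates$male_id, c("a", "b"))
  expect_setequal(without[[1]]$candidates$male_id, c("a", "b"))
  # midpoint (200, 150): d to a = sqrt(100^2 + 50^2), to b = same
  d <- sqrt(100^2 + 50^2)
  expect_equal(with_pb[[1]]$candidates$C - without[[1]]$candidates$C,
               rep(exp(-d / 200), 2))
})

test_that("choice events round-trip through the flat CSV schema", {
  sim <- simulate_study(simulation_config(seed = 22))
  path <- withr::local_tempfile(fileext = ".csv")
  write_choices_csv(sim$events, path)
  back <- read_choices_csv(path)
  expect_equal(length(back), length(sim$events))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$candidates$H, sim$events[[i]]$candidates$H)
    expect_equal(back[[i]]$candidates$C, sim$events[[i]]$candidates$C)
    expect_equal(back[[i]]$chosen, sim$events[[i]]$chosen)
    expect_equal(back[[i]]$female_id, sim$events[[i]]$female_id)
  }
})
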