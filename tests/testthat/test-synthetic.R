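test_that("every generator is byte-identical under a fixed seed", {
  cfg <- simulation_config(seed = 9)
  expect_identical(gen_landscape(cfg, "EW"), gen_landscape(cfg, "EW"))
  land <- gen_landscape(cfg, "EW")
  expect_identical(gen_nests(cfg, land, "EW"), gen_nests(cfg, land, "EW"))
  pb <- gen_playbacks(cfg, "EW", 2017, 2, 3)
  expect_identical(pb, gen_playbacks(cfg, "EW", 2017, 2, 3))
  prox <- build_proximity_raster(pb, cfg$window, "all")
  p1 <- gen_male_pattern(cfg, land, prox, "EW", 2017)
  p2 <- gen_male_pattern(cfg, land, prox, "EW", 2017)
  expect_identical(p1, p2)
  # different sites fork different streams
  expect_false(identical(gen_landscape(cfg, "EW"), gen_landscape(cfg, "LB")))
})

test_that("landscape heterogeneity behaves as configured", {
  cfg0 <- simulation_config(seed = 9, hotspot_count = 0)
  r0 <- gen_landscape(cfg0)
  expect_true(all(r0$values == cfg0$floor))
  # hotspot scale -> infinity flattens the surface: CV decreases to ~0
  cvs <- vapply(c(100, 1000, 10000), function(sc) {
    cfg <- simulation_config(seed = 9, hotspot_scale = sc)
    r <- gen_landscape(cfg)
    stats::sd(r$values) / mean(r$values)
  }, numeric(1))
  expect_true(all(diff(cvs) < 0))
  expect_lt(cvs[3], 0.01)
  expect_true(all(gen_landscape(simulation_config(seed = 3))$values > 0))
})

test_that("nests are drawn proportionally to the surface and stay inside", {
  cfg <- simulation_config(seed = 10, nests_per_year = 0)
  land <- gen_landscape(cfg)
  expect_equal(nrow(gen_nests(cfg, land)), 0)

  # two-level surface, equal areas of value 1 and 3: expect 75% in the
  # high half (multinomial expectation 3/4)
  cfg <- simulation_config(seed = 10, window_size = c(1000, 1000),
                           nests_per_year = 10000, years = 2020)
  r <- raster_from_window(cfg$window, cell = 10, fill = 1)
  r$values[, 51:100] <- 3
  nests <- gen_nests(cfg, r)
  frac_high <- mean(nests$x >= 500)
  expect_lt(abs(frac_high - 0.75), 0.02)
  expect_true(all(inside_window(nests$x, nests$y, cfg$window)))
  expect_true(all(nests$clutch_size >= 1))
})

test_that("thinned settlement counts are Poisson with the intended mean", {
  # homogeneous case: beta0 = ln(50/|W|), covariate effects zero
  cfg <- simulation_config(seed = 11)
  cfg$true_beta <- c(log(50 / window_area(cfg$window)), 0, 0)
  hab <- gen_landscape(cfg)
  counts <- vapply(1:500, function(r) {
    c2 <- cfg; c2$seed <- 11000 + r
    gen_male_pattern(c2, hab, NULL)$n
  }, integer(1))
  expect_lt(abs(mean(counts) - 50), 1)  # MC error ~0.32
  # index-of-dispersion test against Poisson at the 1% level
  disp <- (length(counts) - 1) * var(counts) / mean(counts)
  p <- stats::pchisq(disp, df = length(counts) - 1)
  expect_gt(min(p, 1 - p), 0.005)
  pat <- gen_male_pattern(cfg, hab, NULL)
  expect_true(all(inside_window(pat$x, pat$y, cfg$window)))
})

test_that("playback attraction pulls settlement towards stations", {
  cfg <- simulation_config(seed = 12)
  hab <- gen_landscape(simulation_config(seed = 12, hotspot_count = 0))
  pb <- gen_playbacks(cfg, "EW", 2017, 4, 7)
  prox <- build_proximity_raster(pb, cfg$window, "all")
  mid <- playback_midpoints(pb)
  mean_nearest <- function(beta_prox, seeds) {
    mean(unlist(lapply(seeds, function(s) {
      c2 <- cfg; c2$seed <- s
      c2$true_beta <- c(NA, 0, beta_prox)
      p <- gen_male_pattern(c2, hab, prox, expected_males = 40)
      vapply(seq_len(p$n), function(i)
        min(sqrt((mid$x - p$x[i])^2 + (mid$y - p$y[i])^2)), numeric(1))
    })))
  }
  expect_lt(mean_nearest(4, 1:20), mean_nearest(0, 1:20))
})

test_that("choice frequencies are uniform when both exponents are zero", {
  cfg <- simulation_config(seed = 13, n_choices = 10000, n_females = 10000)
  cfg$true_alpha <- c(0, 0)
  win <- cfg$window
  hab <- gen_landscape(cfg)
  males <- point_pattern(c(100, 300, 500, 700, 900),
                         c(500, 500, 500, 500, 500), win)
  ev <- gen_choice_events(cfg, males, hab, NULL, n_events = 10000)
  counts <- tabulate(vapply(ev, `[[`, integer(1), "chosen"), 5)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("a single candidate is always chosen; extreme alpha1 selects max H", {
  cfg <- simulation_config(seed = 14, n_choices = 200)
  hab <- gen_landscape(cfg)
  lone <- point_pattern(500, 500, cfg$window)
  ev <- gen_choice_events(cfg, lone, hab, NULL, n_events = 200)
  expect_true(all(vapply(ev, `[[`, integer(1), "chosen") == 1L))

  # softmax limit: alpha1 = 10 with distinct H concentrates on max H
  cfg2 <- simulation_config(seed = 15, n_choices = 10000,
                            n_females = 10000)
  cfg2$true_alpha <- c(10, 0)
  r <- raster_from_window(cfg2$window, cell = 10, fill = 1)
  xs <- c(105, 305, 505, 705, 905)
  vals <- c(1, 1.2, 1.5, 2, 4)
  for (i in seq_along(xs)) r$values[51, (xs[i] + 5) / 10] <- vals[i]
  males <- point_pattern(xs, rep(505, 5), cfg2$window)
  ev <- gen_choice_events(cfg2, males, r, NULL, n_events = 10000)
  expect_gt(mean(vapply(ev, `[[`, integer(1), "chosen") == 5L), 0.99)
})

test_that("the choice sampler matches choice_probabilities on a fixed scene", {
  cfg <- simulation_config(seed = 16, n_choices = 20000,
                           n_females = 20000)
  hab <- gen_landscape(cfg)
  males <- point_pattern(c(150, 250, 450, 650, 850),
                         c(200, 700, 400, 600, 300), cfg$window)
  pb <- gen_playbacks(cfg, "S", NA, 2, 2)
  ev <- gen_choice_events(cfg, males, hab, pb, n_events = 20000)
  p <- choice_probabilities(ev[[1]], cfg$true_alpha[1], cfg$true_alpha[2])
  counts <- tabulate(vapply(ev, `[[`, integer(1), "chosen"), 5)
  expect_gt(stats::chisq.test(counts, p = p)$p.value, 0.01)
})

test_that("the full study simulation is deterministic and study-sized", {
  sim <- simulate_study(simulation_config(seed = 17))
  sim2 <- simulate_study(simulation_config(seed = 17))
  expect_identical(sim$nests, sim2$nests)
  expect_identical(sim$events, sim2$events)
  expect_identical(sim$territories, sim2$territories)
  expect_equal(length(sim$events), 59)
  expect_equal(length(unique(vapply(sim$events, `[[`, character(1),
                                    "female_id"))), 50)
  expect_equal(length(sim$scenes), 5)
  # settled males within each site-year are unique points
  for (sc in sim$scenes)
    expect_equal(anyDuplicated(sc$males$male_id), 0)
})
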