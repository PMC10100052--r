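test_that("quadrature counting weights follow the Berman-Turner rule", {
  win <- bbox_window(0, 100, 0, 100)
  # empty pattern, 10 m dummy grid: 100 dummies each weighing 100 m^2
  q0 <- make_quadrature(point_pattern(numeric(0), numeric(0), win),
                        dummy_spacing = 10)
  expect_equal(nrow(q0$points), 100)
  expect_true(all(q0$points$w == 100))
  expect_true(all(q0$points$z == 0))

  # one data point sharing a tile with its dummy: both get tile area / 2
  q1 <- make_quadrature(point_pattern(3, 4, win), dummy_spacing = 10)
  intile <- q1$points$x < 10 & q1$points$y < 10
  expect_equal(sum(intile), 2)
  expect_true(all(q1$points$w[intile] == 50))
  expect_true(all(q1$points$w[!intile] == 100))
  expect_error(make_quadrature(point_pattern(3, 4, win),
                               dummy_spacing = 0), "positive")
})

test_that("quadrature weights tile the window area even for awkward extents", {
  set.seed(31)
  for (dims in list(c(100, 100), c(1000, 700), c(95, 130))) {
    win <- bbox_window(0, dims[1], 0, dims[2])
    pp <- point_pattern(runif(17, 0, dims[1]), runif(17, 0, dims[2]), win)
    q <- make_quadrature(pp, dummy_spacing = 10)
    expect_lt(abs(sum(q$points$w) - window_area(win)) / window_area(win),
              0.01)
    expect_equal(sum(q$points$z), 17)
  }
})

test_that("the null model recovers the homogeneous closed-form MLE", {
  set.seed(32)
  win <- bbox_window(0, 1000, 0, 1000)
  pp <- point_pattern(runif(50, 0, 1000), runif(50, 0, 1000), win)
  f <- fit_ppm(list(pp), list(list()), model = character(0))
  expect_lt(abs(f$coefficients[["(Intercept)"]] - log(50 / 1e6)), 1e-3)
  expect_equal(f$k, 1)
  # score equation for the intercept: fitted total intensity = point count
  q <- make_quadrature(pp, dummy_spacing = 10)
  expect_equal(sum(q$points$w * exp(f$coefficients[[1]])), 50,
               tolerance = 1e-6)
})

test_that("the IRLS solution matches a weighted Poisson GLM oracle", {
  cfg <- simulation_config(seed = 33)
  hab <- gen_landscape(cfg, "EW")
  pb <- gen_playbacks(cfg, "EW", 2017, 4, 7)
  prox <- build_proximity_raster(pb, cfg$window, "all")
  pat <- gen_male_pattern(cfg, hab, prox, "EW", 2017, expected_males = 30)
  fit <- fit_ppm(list(pat), list(list(hab = hab, prox.all = prox)),
                 model = c("hab", "prox.all"))
  q <- make_quadrature(pat, list(hab = hab, prox.all = prox), 10)
  d <- q$points
  g <- suppressWarnings(
    stats::glm(I(z / w) ~ hab + prox.all, family = poisson, weights = w,
               data = d))
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-8)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(sqrt(diag(vcov(g)))), tolerance = 1e-5)
})

test_that("the quadrature log-likelihood agrees with a 1 m fine-grid evaluation", {
  cfg <- simulation_config(seed = 34, window_size = c(200, 200),
                           hotspot_count = 2, hotspot_scale = 60)
  hab <- gen_landscape(cfg)
  cfg$true_beta <- c(NA, 0.109, 0)
  pat <- gen_male_pattern(cfg, hab, NULL, expected_males = 25)
  fit <- fit_ppm(list(pat), list(list(hab = hab)), model = "hab")
  b <- fit$coefficients
  # independent oracle: sum log lambda at data + 1 m Riemann integral
  fx <- seq(0.5, 199.5, by = 1)
  grid <- expand.grid(x = fx, y = fx)
  lam <- exp(b[[1]] + b[["hab"]] * sample_raster(hab, grid$x, grid$y))
  oracle <- sum(b[[1]] + b[["hab"]] * sample_raster(hab, pat$x, pat$y)) -
    sum(lam) * 1
  expect_lt(abs(fit$loglik - oracle) / abs(oracle), 1e-3)
})

test_that("doubling the dummy density barely moves the estimates", {
  cfg <- simulation_config(seed = 35)
  hab <- gen_landscape(cfg, "EW")
  pb <- gen_playbacks(cfg, "EW", 2017, 4, 7)
  prox <- build_proximity_raster(pb, cfg$window, "all")
  pat <- gen_male_pattern(cfg, hab, prox, "EW", 2017, expected_males = 30)
  cs <- list(list(hab = hab, prox.all = prox))
  f10 <- fit_ppm(list(pat), cs, model = c("hab", "prox.all"),
                 dummy_spacing = 10)
  f5 <- fit_ppm(list(pat), cs, model = c("hab", "prox.all"),
                dummy_spacing = 5)
  expect_lt(max(abs(f10$coefficients - f5$coefficients)), 1e-2)
})

test_that("the pooled fit is invariant to pattern and point order", {
  scenes <- study_scenes(42)
  pats <- lapply(scenes, `[[`, "males")
  cs <- lapply(scenes, function(sc) list(hab = sc$hab, prox.all = sc$prox))
  keep <- vapply(pats, function(p) p$n > 0, logical(1))
  f1 <- fit_ppm(pats[keep], cs[keep], model = c("hab", "prox.all"))
  perm <- rev(seq_len(sum(keep)))
  f2 <- fit_ppm(pats[keep][perm], cs[keep][perm],
                model = c("hab", "prox.all"))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  # shuffling points within a pattern changes nothing either
  p1 <- pats[keep][[1]]
  o <- sample(p1$n)
  p1s <- point_pattern(p1$x[o], p1$y[o], p1$window, p1$site, p1$year)
  f3 <- fit_ppm(c(list(p1s), pats[keep][-1]), cs[keep],
                model = c("hab", "prox.all"))
  expect_equal(f3$coefficients, f1$coefficients, tolerance = 1e-8)
})

test_that("candidate-set fitting produces a coherent comparison table", {
  scenes <- study_scenes(42)
  pats <- lapply(scenes, `[[`, "males")
  cs <- lapply(scenes, function(sc)
    list(hab = sc$hab,
         prox.all = sc$prox,
         prox.lc = build_proximity_raster(sc$playbacks,
                                          simulation_config()$window,
                                          "low_only")))
  keep <- vapply(pats, function(p) p$n > 0, logical(1))
  res <- fit_ppm_candidates(pats[keep], cs[keep])
  expect_equal(nrow(res$comparison), 6)
  expect_equal(sum(res$comparison$weight), 1)
  expect_equal(res$comparison$delta[1], 0)
  # the null fit has exactly the homogeneous deviance structure
  expect_equal(res$fits[["null"]]$k, 1)
})

test_that("range standardization is exp(beta x range)", {
  expect_equal(relative_importance(0, c(-3, 17)), 1.0)
  expect_equal(relative_importance(1.773, c(0, 1)), exp(1.773))
  expect_equal(relative_importance(0.109, c(0, 10)), exp(1.09))
})
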