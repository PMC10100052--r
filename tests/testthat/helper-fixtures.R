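# Shared fixtures, all built in code at test time.

# A constant-valued raster covering a window.
const_raster <- function(window, value = 1, cell = 10) {
  raster_from_window(window, cell = cell, fill = value)
}

# A small hand-laid choice event: H and C given directly.
toy_event <- function(H, C = rep(1, length(H)), chosen = 1) {
  choice_event(
    data.frame(male_id = sprintf("m%d", seq_along(H)),
               x = 100 * seq_along(H), y = 0 * H, H = H, C = C),
    chosen = chosen)
}

toy_events <- function(n, H, C = rep(1, length(H)), chosen = 1) {
  structure(replicate(n, toy_event(H, C, chosen), simplify = FALSE),
            class = "choice_events")
}

# Study-like scenes at a fixed generator seed, reused across stochastic
# tests (the scenes are the fixed experimental layout; replicates redraw
# males and/or choices on top of them).
study_scenes <- local({
  cache <- new.env()
  function(seed = 42) {
    key <- as.character(seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- gen_study_scenes(simulation_config(seed = seed))
    cache[[key]]
  }
})

# Redraw the study's choice events on fixed scenes with a fresh seed and
# the given true exponents.
redraw_choices <- function(scenes, seed, true_alpha, n_events) {
  cfg <- simulation_config(seed = seed)
  cfg$true_alpha <- true_alpha
  gen_study_choices(cfg, scenes, n_events = n_events)
}

# Redraw the settled-male patterns on fixed scenes with a common
# generative intercept calibrated so the total expected count is `target`
# across scenes (the fitted model's own structure: one shared intercept).
redraw_patterns_common_b0 <- function(scenes, seed, beta_hab, beta_prox,
                                      target = 50) {
  cell2 <- scenes[[1]]$hab$cell^2
  tot <- sum(vapply(scenes, function(sc)
    sum(exp(beta_hab * sc$hab$values + beta_prox * sc$prox$values)) * cell2,
    numeric(1)))
  b0 <- log(target / tot)
  cfg <- simulation_config(seed = seed)
  cfg$true_beta <- c(b0, beta_hab, beta_prox)
  lapply(scenes, function(sc)
    gen_male_pattern(cfg, sc$hab, sc$prox, sc$site, sc$year))
}
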