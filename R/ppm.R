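#' Settled-male point pattern for one site-year
#'
#' The unit of point-process fitting: the cumulative settlement locations of
#' males within one site and year, inside a rectangular window. One point
#' per male (the preprocess step enforces this independence requirement).
#'
#' @param x,y point coordinates in metres.
#' @param window a [bbox_window()].
#' @param site,year labels.
#' @param male_id optional identifiers (defaults to \code{m001, ...}).
#' @return Object of class \code{"point_pattern"}.
#' @export
point_pattern <- function(x, y, window, site = "S", year = NA,
                          male_id = NULL) {
  stopifnot(length(x) == length(y))
  if (length(x) > 0 && !all(inside_window(x, y, window)))
    stop("all points must lie inside the window")
  if (is.null(male_id))
    male_id <- sprintf("m%03d", seq_along(x))
  structure(list(site = site, year = year, window = window,
                 x = as.numeric(x), y = as.numeric(y),
                 male_id = male_id, n = length(x)),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point_pattern: %d points, site %s year %s, window %g x %g m\n",
              x$n, x$site, as.character(x$year),
              x$window$xmax - x$window$xmin, x$window$ymax - x$window$ymin))
  invisible(x)
}

#' Berman-Turner quadrature scheme
#'
#' Approximates the Poisson point-process likelihood by a weighted sum over
#' quadrature points: the data points plus a regular grid of dummy points at
#' spacing \code{dummy_spacing}. The window is tiled by the dummy grid's
#' cells and each quadrature point receives the counting weight
#' \eqn{w_j = \mathrm{tile\ area} / \mathrm{points\ in\ tile}}, so the
#' weights sum exactly to the window area. Tiles are half-open,
#' \code{[x0, x0 + s)} in each coordinate; a point on the window's far edge
#' belongs to the last tile. Covariate values are attached to every
#' quadrature point by nearest-cell sampling.
#'
#' @param pattern a [point_pattern()].
#' @param covariates named list of [grid_raster()]s covering the window.
#' @param dummy_spacing dummy grid spacing in metres.
#' @return Object of class \code{"quad_scheme"}: a list with a data frame
#'   \code{points} (columns \code{x}, \code{y}, \code{z} data indicator,
#'   \code{w} weight in square metres, plus one column per covariate) and
#'   the window.
#' @export
make_quadrature <- function(pattern, covariates = list(),
                            dummy_spacing = 10) {
  if (dummy_spacing <= 0) stop("dummy_spacing must be positive")
  win <- pattern$window
  s <- dummy_spacing
  ntx <- ceiling((win$xmax - win$xmin) / s)
  nty <- ceiling((win$ymax - win$ymin) / s)
  # tile widths, allowing the window extent not to be a multiple of s
  wx <- pmin(s, win$xmax - win$xmin - (seq_len(ntx) - 1) * s)
  wy <- pmin(s, win$ymax - win$ymin - (seq_len(nty) - 1) * s)
  dx <- win$xmin + (seq_len(ntx) - 1) * s + wx / 2
  dy <- win$ymin + (seq_len(nty) - 1) * s + wy / 2
  dummies <- expand.grid(x = dx, y = dy)
  qx <- c(pattern$x, dummies$x)
  qy <- c(pattern$y, dummies$y)
  z <- c(rep(1L, pattern$n), rep(0L, nrow(dummies)))
  # tile index of every quadrature point (half-open convention)
  ix <- pmin(floor((qx - win$xmin) / s) + 1L, ntx)
  iy <- pmin(floor((qy - win$ymin) / s) + 1L, nty)
  tile <- (iy - 1L) * ntx + ix
  area <- (wx[ix] * wy[iy])
  cnt <- tabulate(tile, nbins = ntx * nty)
  w <- area / cnt[tile]
  pts <- data.frame(x = qx, y = qy, z = z, w = w)
  for (nm in names(covariates))
    pts[[nm]] <- sample_raster(covariates[[nm]], qx, qy)
  structure(list(points = pts, window = win,
                 n_data = pattern$n, dummy_spacing = s),
            class = "quad_scheme")
}

#' Fit a loglinear Poisson point-process model across site-year patterns
#'
#' Maximises the pooled Berman-Turner approximation to the Poisson process
#' log-likelihood,
#' \deqn{\ell \approx \sum_j w_j (y_j \log\lambda_j - \lambda_j), \quad
#'       y_j = z_j / w_j, \quad
#'       \lambda(u) = \exp(\beta_0 + \sum_k \beta_k S_k(u)),}
#' jointly over several point patterns with all coefficients, including the
#' intercept, shared across patterns. The maximisation is Newton iteration
#' on the weighted-Poisson score (equivalently iteratively reweighted least
#' squares for the log link), run to a gradient norm below \code{tol};
#' the coefficient covariance is the inverse Fisher information.
#'
#' The reported log-likelihood is \eqn{\sum_{data} \log\hat\lambda -
#' \sum_j w_j \hat\lambda_j}, the quadrature approximation of
#' \eqn{\sum \log\lambda - \int_W \lambda\,du} (without the 1/n! constant).
#' AICc uses the total number of data points across patterns as the sample
#' size.
#'
#' @param patterns list of [point_pattern()]s (or a single one).
#' @param covariate_sets list parallel to \code{patterns}; each element a
#'   named list of [grid_raster()]s for that pattern's window. Every name in
#'   \code{model} must be present in every element.
#' @param model character vector of covariate names to include;
#'   \code{character(0)} fits the homogeneous (null) model.
#' @param dummy_spacing dummy grid spacing in metres.
#' @param per_pattern_intercept if \code{TRUE}, each pattern receives its
#'   own intercept (sensitivity analysis); default is a single shared
#'   intercept.
#' @param tol convergence tolerance on the score norm.
#' @param max_iter maximum Newton iterations.
#' @return Object of class \code{"ppm_fit"} with elements
#'   \code{coefficients}, \code{vcov}, \code{loglik}, \code{n_points},
#'   \code{k}, \code{aicc}, \code{model}, \code{converged}, \code{iter}.
#' @export
fit_ppm <- function(patterns, covariate_sets, model = character(0),
                    dummy_spacing = 10, per_pattern_intercept = FALSE,
                    tol = 1e-8, max_iter = 100) {
  if (inherits(patterns, "point_pattern")) {
    patterns <- list(patterns)
    if (length(model) > 0 && !is.null(names(covariate_sets)) &&
        all(model %in% names(covariate_sets)))
      covariate_sets <- list(covariate_sets)
  }
  np <- length(patterns)
  if (missing(covariate_sets) || is.null(covariate_sets))
    covariate_sets <- rep(list(list()), np)
  stopifnot(length(covariate_sets) == np)
  rows <- vector("list", np)
  for (p in seq_len(np)) {
    covs <- covariate_sets[[p]][model]
    if (length(model) > 0 && any(!model %in% names(covariate_sets[[p]])))
      stop("covariate_sets[[", p, "]] is missing a model covariate")
    q <- make_quadrature(patterns[[p]], covs, dummy_spacing)
    q$points$pattern <- p
    rows[[p]] <- q$points
  }
  quad <- do.call(rbind, rows)

  if (per_pattern_intercept && np > 1) {
    Xint <- stats::model.matrix(~ 0 + factor(quad$pattern))
    colnames(Xint) <- sprintf("(Intercept).%d", seq_len(np))
  } else {
    Xint <- matrix(1, nrow(quad), 1, dimnames = list(NULL, "(Intercept)"))
  }
  X <- cbind(Xint, as.matrix(quad[, model, drop = FALSE]))
  w <- quad$w
  z <- quad$z
  y <- z / w
  n_data <- sum(z)
  k <- ncol(X)

  beta <- c(rep(log(max(n_data, 1) / sum(w)), ncol(Xint)), rep(0, length(model)))
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    if (any(eta > 500))
      stop("PPM fit diverged (separation: fitted intensity unbounded)")
    mu <- exp(eta)
    score <- drop(crossprod(X, w * (y - mu)))
    if (sqrt(sum(score^2)) < tol) { converged <- TRUE; break }
    if (iter > max_iter) break
    info <- crossprod(X, X * (w * mu))
    step <- tryCatch(solve(info, score),
                     error = function(e) stop("PPM fit failed: singular information matrix"))
    # step-halving keeps Newton from overshooting on hard starts
    ll0 <- sum(z * eta) - sum(w * mu)
    h <- 1
    repeat {
      cand <- beta + h * step
      eta1 <- drop(X %*% cand)
      ll1 <- if (any(eta1 > 500)) -Inf else sum(z * eta1) - sum(w * exp(eta1))
      if (ll1 >= ll0 - 1e-12 || h < 1e-6) break
      h <- h / 2
    }
    beta <- beta + h * step
  }
  if (!converged)
    stop(sprintf("PPM fit did not converge in %d iterations", max_iter))
  eta <- drop(X %*% beta)
  mu <- exp(eta)
  info <- crossprod(X, X * (w * mu))
  vc <- solve(info)
  ll <- sum(eta[z == 1L]) - sum(w * mu)
  names(beta) <- colnames(X)
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, vcov = vc, loglik = ll,
                 n_points = n_data, k = k,
                 aicc = aicc(ll, k, n_data),
                 model = model, n_patterns = np,
                 dummy_spacing = dummy_spacing,
                 per_pattern_intercept = per_pattern_intercept,
                 converged = converged, iter = iter),
            class = "ppm_fit")
}

#' @export
print.ppm_fit <- function(x, ...) {
  lab <- if (length(x$model) == 0) "null" else paste(x$model, collapse = " + ")
  cat(sprintf("Poisson point-process model (%s), %d pattern(s), %d points\n",
              lab, x$n_patterns, x$n_points))
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(estimate = x$coefficients, se = se,
                    ci_low = x$coefficients - 1.96 * se,
                    ci_high = x$coefficients + 1.96 * se)
  print(round(tab, 4))
  cat(sprintf("logLik %.3f   AICc %.2f (k = %d, n = %d)\n",
              x$loglik, x$aicc, x$k, x$n_points))
  invisible(x)
}

#' @export
coef.ppm_fit <- function(object, ...) object$coefficients

#' @export
vcov.ppm_fit <- function(object, ...) object$vcov

#' @export
logLik.ppm_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' Wald confidence intervals for PPM coefficients
#' @param object a \code{ppm_fit}.
#' @param parm coefficients to include (default all).
#' @param level confidence level.
#' @param ... unused.
#' @export
confint.ppm_fit <- function(object, parm = NULL, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - zq * se, object$coefficients + zq * se)
  colnames(ci) <- sprintf("%g %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Fit the standard candidate set of settlement models
#'
#' Fits the six candidate models — null, each single covariate, and habitat
#' plus each playback-proximity covariate — and returns the fits together
#' with an AICc comparison table.
#'
#' @inheritParams fit_ppm
#' @param models named list of covariate-name vectors; the default is the
#'   six-model candidate set over \code{hab}, \code{prox.all},
#'   \code{prox.lc}.
#' @return List with elements \code{fits} (named list of \code{ppm_fit}s)
#'   and \code{comparison} (see [delta_and_weights()]).
#' @export
fit_ppm_candidates <- function(patterns, covariate_sets,
                               models = list(
                                 "null" = character(0),
                                 "hab" = "hab",
                                 "prox.all" = "prox.all",
                                 "prox.lc" = "prox.lc",
                                 "hab + prox.all" = c("hab", "prox.all"),
                                 "hab + prox.lc" = c("hab", "prox.lc")),
                               dummy_spacing = 10, ...) {
  fits <- lapply(models, function(m)
    fit_ppm(patterns, covariate_sets, model = m,
            dummy_spacing = dummy_spacing, ...))
  av <- vapply(fits, `[[`, numeric(1), "aicc")
  list(fits = fits, comparison = delta_and_weights(av))
}

#' Range standardization of a fitted coefficient
#'
#' Expresses a loglinear coefficient as the multiplicative change in
#' predicted density across the observed range of its covariate:
#' \code{exp(beta * (max - min))}. A value of, say, 6 means predicted
#' settlement density varies six-fold across the covariate's span.
#'
#' @param beta fitted coefficient (per covariate unit, log-density scale).
#' @param value_range length-2 numeric, the covariate's observed
#'   (min, max) over the analysis windows.
#' @return The density factor, a single number.
#' @export
relative_importance <- function(beta, value_range) {
  stopifnot(is.finite(beta), length(value_range) == 2,
            all(is.finite(value_range)))
  exp(beta * (value_range[2] - value_range[1]))
}

#' Observed range of a covariate over several rasters
#' @param covariate_sets list of named raster lists (as in [fit_ppm()]).
#' @param name covariate name.
#' @return c(min, max) over all cells of all rasters of that name.
#' @export
covariate_range <- function(covariate_sets, name) {
  vals <- unlist(lapply(covariate_sets, function(cs) range(cs[[name]]$values)))
  range(vals)
}
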